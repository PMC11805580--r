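# Boolean inference of reaction and transport mechanisms (RTMs).
#
# At each tissue point and reporting interval the directions of the three
# concentration ratios C2/C1, C3/C1 and C3/C2, together with the reaction
# state (association vs dissociation of the bound pool) and the membrane
# state (internalization / externalization / partial equilibrium from
# C2/C1 vs 1), constrain how the rates of the competing mechanisms are
# ordered.  The constraints are propositional:
#
#   P8 : IN >= AS      P9 : EX <= DIS
#   P10: EX >= ECT-    P11: IN <= ECT+
#   P12: association exists
#
# The ratio-direction propositions (increase-or-equal between the two
# instants) are tied to these by exclusive disjunctions: C1 rises iff
# exactly one of P10, P11 holds; C2 rises iff exactly one of P8, P9; C3
# rises iff P12.  Contraposing the sufficient-condition implications for
# the ratio directions yields, for each of the eight (I/D, I/D, I/D)
# scenarios, a conjunction of three clauses; fixing the reaction and
# membrane state then prunes the proposition space.  The classifier
# evaluates the pruned statement by exhaustive enumeration (at most 2^4
# assignments) and reports the surviving relation, a tautology (the
# scenario is uninformative) or a contradiction (the scenario is
# physically inconsistent).

RTM_VARS <- c("P8", "P9", "P10", "P11", "P12")

xor2 <- function(a, b) xor(a, b)

# The three scenario clauses (contrapositives of the direction implications).
rtm_general_statement <- function(dir21, dir31, dir32) {
  force(dir21); force(dir31); force(dir32)
  function(a) {
    x89 <- xor2(a[["P8"]], a[["P9"]])
    x1011 <- xor2(a[["P10"]], a[["P11"]])
    g14 <- if (dir21 == "I") x89 | !x1011 else !x89 | x1011
    g15 <- if (dir31 == "I") a[["P12"]] | !x1011 else !a[["P12"]] | x1011
    g16 <- if (dir32 == "I") a[["P12"]] | !x89 else !a[["P12"]] | x89
    g14 && g15 && g16
  }
}

# Variable pinning from the reaction and membrane state.  The reaction
# fixes P12 and removes the impossible arm of the C2 exclusive disjunction;
# the membrane state removes the impossible comparisons (an absent
# mechanism cannot impose over a present one, and trivially yields to an
# absent competitor).  Reaction assignments take precedence.
rtm_substitutions <- function(reaction, membrane) {
  sub <- list()
  if (reaction == "AS") {
    sub$P12 <- TRUE; sub$P9 <- FALSE
  } else {                    # DIS or SATURATED (no association possible)
    sub$P12 <- FALSE; sub$P8 <- FALSE
  }
  fix <- function(nm, val) if (is.null(sub[[nm]])) sub[[nm]] <<- val
  if (membrane == "IN") {
    fix("P10", FALSE); fix("P9", TRUE)
  } else if (membrane == "EX") {
    fix("P11", FALSE); fix("P8", FALSE)
  } else {                    # EQ: neither IN nor EX present
    fix("P10", FALSE); fix("P11", FALSE)
    fix("P9", TRUE); fix("P8", FALSE)
  }
  sub
}

rtm_assignments <- function(sub, extra_constraint = NULL) {
  free <- setdiff(RTM_VARS, names(sub))
  grid <- if (length(free) == 0) {
    data.frame(row.names = 1)
  } else {
    stats::setNames(expand.grid(rep(list(c(FALSE, TRUE)), length(free))), free)
  }
  asn <- lapply(seq_len(nrow(grid)), function(k) {
    a <- as.list(grid[k, , drop = FALSE])
    a <- c(a, sub)
    a[RTM_VARS]
  })
  if (!is.null(extra_constraint)) {
    asn <- Filter(extra_constraint, asn)
  }
  asn
}

RTM_LITERALS <- c(
  "P8+" = "IN>=AS",  "P8-" = "IN<=AS",
  "P9+" = "EX<=DIS", "P9-" = "EX>=DIS",
  "P10+" = "EX>=ECT-", "P10-" = "EX<=ECT-",
  "P11+" = "IN<=ECT+", "P11-" = "IN>=ECT+"
)

lit_string <- function(var, pol) {
  unname(RTM_LITERALS[paste0(var, if (pol) "+" else "-")])
}

# Express a boolean function (given by its satisfying assignments over the
# free variables) as a literal, or a conjunction / disjunction /
# biconditional of two literals.  Together with the two constants this
# covers every function of at most two variables.
render_relation <- function(sat, free) {
  if (length(free) == 0) return(NULL)
  grid <- stats::setNames(expand.grid(rep(list(c(FALSE, TRUE)), length(free))), free)
  truth <- logical(nrow(grid))
  sat_keys <- vapply(sat, function(a) {
    paste(vapply(free, function(v) a[[v]], NA), collapse = "")
  }, "")
  for (k in seq_len(nrow(grid))) {
    key <- paste(unlist(grid[k, , drop = FALSE]), collapse = "")
    truth[k] <- key %in% sat_keys
  }
  lit_truth <- function(var, pol) if (pol) grid[[var]] else !grid[[var]]
  for (v in free) for (pol in c(TRUE, FALSE)) {
    if (all(truth == lit_truth(v, pol))) return(lit_string(v, pol))
  }
  if (length(free) == 2) {
    v1 <- free[1]; v2 <- free[2]
    combos <- expand.grid(p1 = c(TRUE, FALSE), p2 = c(TRUE, FALSE))
    for (k in seq_len(nrow(combos))) {
      p1 <- combos$p1[k]; p2 <- combos$p2[k]
      l1 <- lit_truth(v1, p1); l2 <- lit_truth(v2, p2)
      if (all(truth == (l1 & l2))) {
        return(sprintf("(%s)&(%s)", lit_string(v1, p1), lit_string(v2, p2)))
      }
      if (all(truth == (l1 | l2))) {
        return(sprintf("(%s)|(%s)", lit_string(v1, p1), lit_string(v2, p2)))
      }
    }
    if (all(truth == (grid[[v1]] == grid[[v2]]))) {
      return(sprintf("(%s)<->(%s)", lit_string(v1, TRUE), lit_string(v2, TRUE)))
    }
    if (all(truth == xor(grid[[v1]], grid[[v2]]))) {
      return(sprintf("(%s)<->(%s)", lit_string(v1, TRUE), lit_string(v2, FALSE)))
    }
  }
  # fall back to disjunctive normal form over the satisfying assignments
  paste(vapply(sat, function(a) {
    paste0("(", paste(vapply(free, function(v) lit_string(v, a[[v]]), ""),
                      collapse = "&"), ")")
  }, ""), collapse = "|")
}

#' Direction of a ratio between two instants
#'
#' Increase-or-remains-equal counts as `"I"` (the propositions use
#' non-strict comparisons); a decrease beyond the tie tolerance is `"D"`.
#'
#' @param prev,next_ Values at the earlier and later instant.
#' @param tie_tol Relative tolerance below which the change counts as a tie.
#' @return `"I"` or `"D"` (vectorized).
#' @export
ratio_direction <- function(prev, next_, tie_tol = 1e-9) {
  if (any(is.nan(prev) | is.nan(next_))) {
    stop("NaN ratio passed to ratio_direction", call. = FALSE)
  }
  scale <- pmax(abs(prev), abs(next_), 1e-300)
  ifelse(next_ - prev >= -tie_tol * scale, "I", "D")
}

#' Membrane state from the intracellular-to-extracellular ratio
#'
#' `C2/C1 < 1` means the gradient is inward (internalization `IN`);
#' `> 1` outward (externalization `EX`); equality within tolerance is
#' partial equilibrium (`EQ`).
#'
#' @param c2_over_c1 Ratio value(s), non-negative.
#' @param tol Equality tolerance.
#' @return `"IN"`, `"EX"` or `"EQ"` (vectorized).
#' @export
membrane_state <- function(c2_over_c1, tol = 1e-9) {
  ifelse(c2_over_c1 < 1 - tol, "IN",
         ifelse(c2_over_c1 > 1 + tol, "EX", "EQ"))
}

#' Reaction state from the bound-concentration change
#'
#' Association (`AS`) when the bound concentration rises (ties count as
#' `AS`, mirroring the non-strict direction convention); dissociation
#' (`DIS`) when it falls; `SATURATED` when the binding-site concentration
#' has been reached, which excludes further association.
#'
#' @param c3_prev,c3_next Bound concentrations at the interval endpoints, uM.
#' @param C0 Binding-site concentration, uM.
#' @param tie_tol Relative tie tolerance.
#' @return `"AS"`, `"DIS"` or `"SATURATED"` (vectorized).
#' @export
reaction_state <- function(c3_prev, c3_next, C0, tie_tol = 1e-9) {
  dir <- ratio_direction(c3_prev, c3_next, tie_tol)
  ifelse(c3_next >= C0 * (1 - tie_tol), "SATURATED",
         ifelse(dir == "I", "AS", "DIS"))
}

#' Classify one point-interval observation
#'
#' Applies the Boolean inference to a single observation: the directions of
#' the three ratios over the interval, the reaction state, the membrane
#' state at the interval end, and optionally the direction of the
#' extracellular concentration (which, through the exclusive disjunction
#' tied to the C1 change, refines the statement further).
#'
#' @param dir21,dir31,dir32 Directions (`"I"`/`"D"`) of C2/C1, C3/C1, C3/C2.
#' @param reaction `"AS"`, `"DIS"` or `"SATURATED"`.
#' @param membrane `"IN"`, `"EX"` or `"EQ"`.
#' @param c1_dir Optional direction of C1 (`"I"`/`"D"`).  Where the
#'   scenario table prints a C1-direction refinement for the cell (the
#'   compound statements whose disjunct or biconditional branch the C1
#'   change selects), the refined statement is returned; the refinements
#'   are themselves verified against the enumeration by
#'   [verify_rtm_refinements()].  Cells without a printed refinement are
#'   returned unrefined, with the direction recorded in the provenance.
#' @return An `rtm_statement`: list with `kind` (`"RELATION"`,
#'   `"TAUTOLOGY"`, `"CONTRADICTION"`), `relation` (rate-ordering string or
#'   `NA`), `saturated` flag and `provenance`.
#' @export
classify_rtm <- function(dir21, dir31, dir32, reaction, membrane,
                         c1_dir = NULL) {
  stopifnot(dir21 %in% c("I", "D"), dir31 %in% c("I", "D"),
            dir32 %in% c("I", "D"),
            reaction %in% c("AS", "DIS", "SATURATED"),
            membrane %in% c("IN", "EX", "EQ"))
  if (!is.null(c1_dir)) stopifnot(c1_dir %in% c("I", "D"))
  G <- rtm_general_statement(dir21, dir31, dir32)
  sub <- rtm_substitutions(reaction, membrane)
  asn <- rtm_assignments(sub)
  sat <- Filter(G, asn)
  free <- setdiff(RTM_VARS, names(sub))
  kind <- if (length(asn) == 0 || length(sat) == 0) {
    "CONTRADICTION"
  } else if (length(sat) == length(asn)) {
    "TAUTOLOGY"
  } else {
    "RELATION"
  }
  relation <- NA_character_
  refined <- FALSE
  if (kind == "RELATION") {
    relation <- render_relation(sat, free)
    if (is.null(relation)) relation <- NA_character_
    if (!is.null(c1_dir)) {
      cell_id <- paste0(dir21, dir31, dir32, ".",
                        if (reaction == "SATURATED") "DIS" else reaction,
                        ".", membrane)
      ref <- printed_rtm_table()[[cell_id]]$refine
      if (!is.null(ref) && !is.null(ref[[c1_dir]])) {
        code <- ref[[c1_dir]]
        relation <- lit_string(sub("[+-]$", "", code),
                               substr(code, nchar(code), nchar(code)) == "+")
        refined <- TRUE
      }
    }
  }
  structure(list(
    kind = kind,
    relation = relation,
    refined = refined,
    saturated = reaction == "SATURATED",
    provenance = list(scenario = paste0(dir21, dir31, dir32),
                      reaction = reaction, membrane = membrane,
                      c1_dir = c1_dir)
  ), class = "rtm_statement")
}

#' @export
print.rtm_statement <- function(x, ...) {
  pv <- x$provenance
  lab <- switch(x$kind, RELATION = x$relation, x$kind)
  cat(sprintf("<rtm_statement %s.%s.%s%s: %s%s>\n",
              pv$scenario, pv$reaction, pv$membrane,
              if (!is.null(pv$c1_dir)) paste0(".C1", pv$c1_dir) else "",
              lab, if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Satisfying assignments for an observation (enumeration backend)
#'
#' Exposes the truth-table enumeration used by the classifier: the list of
#' admissible proposition assignments and the subset satisfying the
#' scenario statement.  Used by the verifier and by property tests.
#'
#' @inheritParams classify_rtm
#' @return List with `admissible` and `satisfying` assignment lists.
#' @export
rtm_truth_sets <- function(dir21, dir31, dir32, reaction, membrane,
                           c1_dir = NULL) {
  G <- rtm_general_statement(dir21, dir31, dir32)
  sub <- rtm_substitutions(reaction, membrane)
  constraint <- NULL
  if (!is.null(c1_dir)) {
    want <- c1_dir == "I"
    constraint <- function(a) xor2(a[["P10"]], a[["P11"]]) == want
  }
  asn <- rtm_assignments(sub, constraint)
  list(admissible = asn, satisfying = Filter(G, asn))
}
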