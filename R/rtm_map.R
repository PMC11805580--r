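# Classification of a simulated trajectory: one RTM statement per grid
# point and consecutive reporting interval.

interp_to_grid <- function(F, r_from, r_to) {
  if (length(r_from) == length(r_to) && all(abs(r_from - r_to) < 1e-15)) {
    return(F)
  }
  apply(F, 2, function(col) stats::approx(r_from, col, xout = r_to, rule = 2)$y)
}

#' Classify every point and reporting interval of a trajectory
#'
#' For each pair of consecutive snapshots and each grid point, builds the
#' interval observation (directions of C2/C1, C3/C1, C3/C2; reaction state
#' from the bound-concentration change; membrane state from C2/C1 at the
#' interval end; direction of C1) and applies the Boolean classifier.  If
#' a remesh occurred between the snapshots, the earlier fields are
#' interpolated onto the later radial grid.  Points where a ratio
#' denominator falls below `eps_div` at either endpoint are flagged
#' `UNDEFINED` rather than classified.
#'
#' @param traj A `cord_trajectory` (at least two snapshots).
#' @param tie_tol Relative tie tolerance (default from the run config).
#' @param eps_div Denominator guard in uM (default from the run config).
#' @param membrane_at `"end"` evaluates the membrane state at the interval
#'   end; `"both"` requires both endpoints to agree and tags disagreement
#'   as a `TRANSITION` (`"A to B"`).
#' @param refine_c1 Apply the C1-direction refinement to the statements.
#' @return A tibble with one row per (interval, point): `t_start_h`,
#'   `t_end_h`, `r`, `z`, `code`, `kind`, `relation`, `c1_dir`,
#'   `saturated`.
#' @export
rtm_map <- function(traj, tie_tol = NULL, eps_div = NULL,
                    membrane_at = c("end", "both"), refine_c1 = TRUE) {
  stopifnot(inherits(traj, "cord_trajectory"))
  membrane_at <- match.arg(membrane_at)
  if (length(traj$snapshots) < 2) {
    stop("need at least two snapshots to classify intervals", call. = FALSE)
  }
  tie_tol <- tie_tol %||% traj$params$numerics$tie_tol
  eps_div <- eps_div %||% traj$params$numerics$eps_div
  C0 <- traj$params$transport$C0
  memo <- new.env(parent = emptyenv())
  classify_memo <- function(key, d21, d31, d32, reac, memb, c1d) {
    st <- memo[[key]]
    if (is.null(st)) {
      st <- classify_rtm(d21, d31, d32, reac, memb,
                         c1_dir = if (refine_c1) c1d else NULL)
      memo[[key]] <- st
    }
    st
  }
  out <- vector("list", length(traj$snapshots) - 1L)
  for (k in seq_len(length(traj$snapshots) - 1L)) {
    s0 <- traj$snapshots[[k]]; s1 <- traj$snapshots[[k + 1L]]
    C1a <- interp_to_grid(s0$C1, s0$r, s1$r); C1b <- s1$C1
    C2a <- interp_to_grid(s0$C2, s0$r, s1$r); C2b <- s1$C2
    C3a <- interp_to_grid(s0$C3, s0$r, s1$r); C3b <- s1$C3
    ok <- C1a > eps_div & C1b > eps_div & C2a > eps_div & C2b > eps_div
    grid <- expand.grid(ri = seq_along(s1$r), zi = seq_along(s1$z))
    n <- nrow(grid)
    code <- character(n); kind <- character(n); relation <- rep(NA_character_, n)
    c1dir <- character(n); satur <- logical(n)
    for (q in seq_len(n)) {
      i <- grid$ri[q]; j <- grid$zi[q]
      if (!ok[i, j]) {
        code[q] <- "UNDEFINED"; kind[q] <- "UNDEFINED"; c1dir[q] <- NA_character_
        next
      }
      r21a <- C2a[i, j] / C1a[i, j]; r21b <- C2b[i, j] / C1b[i, j]
      r31a <- C3a[i, j] / C1a[i, j]; r31b <- C3b[i, j] / C1b[i, j]
      r32a <- C3a[i, j] / C2a[i, j]; r32b <- C3b[i, j] / C2b[i, j]
      d21 <- ratio_direction(r21a, r21b, tie_tol)
      d31 <- ratio_direction(r31a, r31b, tie_tol)
      d32 <- ratio_direction(r32a, r32b, tie_tol)
      reac <- reaction_state(C3a[i, j], C3b[i, j], C0, tie_tol)
      c1d <- ratio_direction(C1a[i, j], C1b[i, j], tie_tol)
      memb_end <- membrane_state(r21b, tie_tol)
      if (membrane_at == "both") {
        memb_start <- membrane_state(r21a, tie_tol)
        if (memb_start != memb_end) {
          sa <- classify_memo(paste(d21, d31, d32, reac, memb_start, c1d),
                              d21, d31, d32, reac, memb_start, c1d)
          sb <- classify_memo(paste(d21, d31, d32, reac, memb_end, c1d),
                              d21, d31, d32, reac, memb_end, c1d)
          code[q] <- paste0(d21, d31, d32, ".", reac, ".",
                            memb_start, ">", memb_end)
          kind[q] <- "TRANSITION"
          relation[q] <- paste(sa$kind %||% "", "to", sb$kind)
          relation[q] <- paste(
            if (sa$kind == "RELATION") sa$relation else sa$kind, "to",
            if (sb$kind == "RELATION") sb$relation else sb$kind)
          c1dir[q] <- c1d
          next
        }
      }
      st <- classify_memo(paste(d21, d31, d32, reac, memb_end, c1d),
                          d21, d31, d32, reac, memb_end, c1d)
      code[q] <- paste0(d21, d31, d32, ".", reac, ".", memb_end)
      kind[q] <- st$kind
      relation[q] <- st$relation
      c1dir[q] <- c1d
      satur[q] <- st$saturated
    }
    out[[k]] <- tibble::tibble(
      t_start_h = s0$t / SEC_PER_HOUR, t_end_h = s1$t / SEC_PER_HOUR,
      r = s1$r[grid$ri], z = s1$z[grid$zi],
      code = code, kind = kind, relation = relation,
      c1_dir = c1dir, saturated = satur)
  }
  dplyr::bind_rows(out)
}

#' Legend for RTM map codes
#'
#' @param map A tibble produced by [rtm_map()].
#' @return A tibble mapping each distinct `code` to its `kind` and
#'   human-readable `relation`.
#' @export
rtm_legend <- function(map) {
  dplyr::distinct(map[, c("code", "kind", "relation")])
}
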