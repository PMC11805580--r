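# Simulation campaign fixtures and the command-line entry point.

#' The full simulation campaign
#'
#' The Cartesian product of the three electric field levels (0, 46, 70
#' kV/m), the three inlet blood velocities (1e-4, 1e-3, 1e-2 m/s) and the
#' two pharmacokinetic profiles: 18 deterministic scenarios.
#'
#' @return A tibble with columns `id`, `E` (V/m), `lambda_inl` (m/s), `pk`.
#' @examples
#' campaign_scenarios()
#' @export
campaign_scenarios <- function() {
  grid <- expand.grid(E = c(0, 46e3, 70e3),
                      lambda_inl = c(1e-4, 1e-3, 1e-2),
                      pk = c("TPK", "MPK"),
                      stringsAsFactors = FALSE)
  tibble::tibble(
    id = sprintf("E%g_L%g_%s", grid$E / 1e3, grid$lambda_inl, grid$pk),
    E = grid$E, lambda_inl = grid$lambda_inl, pk = grid$pk)
}

#' Ready-to-run configuration for a campaign scenario
#'
#' Builds a `cord_params` for a scenario id (or a one-row scenario tibble)
#' at one of three problem sizes: `"smoke"` (coarse grid, 1 h horizon, for
#' quick checks), `"desk"` (medium grid, full 24 h treatment) and `"full"`
#' (fine, convergence-checked grid).
#'
#' @param scenario A scenario id string from [campaign_scenarios()], or a
#'   one-row data frame with columns `E`, `lambda_inl`, `pk`.
#' @param scale `"smoke"`, `"desk"` or `"full"`.
#' @return A validated `cord_params`.
#' @export
quickrun_config <- function(scenario, scale = c("desk", "smoke", "full")) {
  scale <- match.arg(scale)
  if (is.character(scenario)) {
    sc <- campaign_scenarios()
    row <- sc[sc$id == scenario, ]
    if (nrow(row) != 1) stop("unknown scenario id: ", scenario, call. = FALSE)
  } else {
    row <- tibble::as_tibble(scenario)
    stopifnot(nrow(row) == 1, all(c("E", "lambda_inl", "pk") %in% names(row)))
  }
  num <- switch(scale,
    smoke = list(n_r = 13, n_z = 5, dt = 30,
                 report_times = c(0, 0.25, 0.5, 0.75, 1) * SEC_PER_HOUR),
    desk = list(n_r = 31, n_z = 13, dt = 10),
    full = list(n_r = 61, n_z = 25, dt = 5))
  horizon <- if (scale == "smoke") SEC_PER_HOUR else 24 * SEC_PER_HOUR
  p <- cord_params(
    protocol = list(E = row$E, T_chemo = horizon,
                    session_times = if (row$E > 0) {
                      st <- seq(0, 20, by = 4) * SEC_PER_HOUR
                      st[st <= horizon]
                    } else {
                      seq(0, 20, by = 4) * SEC_PER_HOUR
                    }),
    blood = list(lambda_inl = row$lambda_inl),
    pk = list(kind = row$pk),
    numerics = num)
  p
}

run_names <- function() c("simulate", "pk", "verify-logic", "metrics", "campaign")

#' Command-line entry point
#'
#' Thin dispatcher behind the `cordsim` script shipped in `inst/cli`.
#' Subcommands: `simulate` (run a scenario and persist the trajectory),
#' `pk` (tabulate an inlet profile as CSV), `verify-logic` (print the
#' scenario-table verification), `metrics` (uniformity / crossing /
#' exposure report for a stored trajectory) and `campaign` (list the 18
#' scenarios).
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code (0 on success), invisibly.
#' @export
cordsim_main <- function(argv = character()) {
  usage <- paste0(
    "usage: cordsim <command> [options]\n",
    "commands:\n",
    "  simulate --scenario ID [--scale smoke|desk|full] [--config FILE] --out DIR\n",
    "  pk --profile TPK|MPK [--until SECONDS] [--by SECONDS]\n",
    "  verify-logic\n",
    "  metrics --traj DIR [--out DIR]\n",
    "  campaign\n")
  if (length(argv) == 0 || !(argv[1] %in% run_names())) {
    cat(usage)
    return(invisible(if (length(argv) == 0) 0L else 1L))
  }
  cmd <- argv[1]; rest <- argv[-1]
  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) == 1 && i < length(rest)) rest[i + 1] else default
  }
  code <- 0L
  if (cmd == "campaign") {
    print(campaign_scenarios(), n = Inf)
  } else if (cmd == "verify-logic") {
    rep <- verify_rtm_table()
    print(rep, n = Inf)
    ok <- all(rep$entailed) && all(rep$equivalent[!rep$resolution_row])
    cat(sprintf("entailment: %s; equivalence outside resolution rows: %s\n",
                all(rep$entailed), all(rep$equivalent[!rep$resolution_row])))
    code <- if (ok) 0L else 2L
  } else if (cmd == "pk") {
    prof <- opt("--profile", "TPK")
    if (!prof %in% c("TPK", "MPK")) { cat(usage); return(invisible(1L)) }
    until <- as.numeric(opt("--until", "3600"))
    by <- as.numeric(opt("--by", "60"))
    tab <- pk_table(pk_profile(prof), seq(0, until, by = by))
    utils::write.csv(tab, stdout(), row.names = FALSE)
  } else if (cmd == "simulate") {
    out <- opt("--out")
    cfg <- opt("--config")
    scen <- opt("--scenario")
    if (is.null(out) || (is.null(scen) && is.null(cfg))) {
      cat(usage); return(invisible(1L))
    }
    p <- if (!is.null(cfg)) load_config(cfg)
         else tryCatch(quickrun_config(scen, opt("--scale", "desk")),
                       error = function(e) NULL)
    if (is.null(p)) { cat("unknown scenario\n"); return(invisible(1L)) }
    message("running simulation ...")
    traj <- run_cord_simulation(p)
    write_trajectory(traj, out)
    message("trajectory written to ", out)
  } else if (cmd == "metrics") {
    dir <- opt("--traj")
    if (is.null(dir)) { cat(usage); return(invisible(1L)) }
    traj <- read_trajectory(dir)
    uni <- dplyr::bind_rows(uniformity_range(traj, "C2/C1"),
                            uniformity_range(traj, "C3"))
    utils::write.csv(uni, stdout(), row.names = FALSE)
    series <- transvascular_ratio_series(traj)
    cross <- reverse_diffusion_time(series)
    if (nrow(cross) > 0) {
      cat(sprintf("reverse diffusion crossing at %.4f h\n", cross$t_cross_h))
    } else {
      cat("no reverse-diffusion crossing\n")
    }
  }
  invisible(code)
}
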