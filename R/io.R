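# Trajectory persistence: a plain-text directory with the configuration,
# one CSV per cord snapshot and one per vessel snapshot.  Values are
# written with 17 significant digits so a round trip reproduces the
# numbers bit-exactly.

fmt_num <- function(x) sprintf("%.17g", x)

#' Persist a trajectory to a directory
#'
#' Writes `config.yaml`, `times.csv`, and per-snapshot
#' `snapshot_<k>.csv` (columns `r`, `z`, `C1`, `C2`, `C3`) and
#' `vessel_<k>.csv` (columns `z`, `Cv`, `lambda`, `Qleak`) files, plus a
#' `geometry_<k>.csv` with the scalar geometry state.  The stored text
#' reproduces the in-memory values bit-exactly on re-load.
#'
#' @param traj A `cord_trajectory`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  stopifnot(inherits(traj, "cord_trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_config(traj$params, file.path(dir, "config.yaml"))
  writeLines(c("t", fmt_num(traj$times)), file.path(dir, "times.csv"))
  for (k in seq_along(traj$snapshots)) {
    s <- traj$snapshots[[k]]
    grid <- expand.grid(ri = seq_along(s$r), zi = seq_along(s$z))
    df <- data.frame(
      r = fmt_num(s$r[grid$ri]), z = fmt_num(s$z[grid$zi]),
      C1 = fmt_num(s$C1[cbind(grid$ri, grid$zi)]),
      C2 = fmt_num(s$C2[cbind(grid$ri, grid$zi)]),
      C3 = fmt_num(s$C3[cbind(grid$ri, grid$zi)]))
    utils::write.csv(df, file.path(dir, sprintf("snapshot_%03d.csv", k)),
                     row.names = FALSE, quote = FALSE)
    vf <- data.frame(z = fmt_num(s$z), Cv = fmt_num(s$Cv),
                     lambda = fmt_num(s$lambda), Qleak = fmt_num(s$Qleak))
    utils::write.csv(vf, file.path(dir, sprintf("vessel_%03d.csv", k)),
                     row.names = FALSE, quote = FALSE)
    gf <- data.frame(t = fmt_num(s$t), r_v = fmt_num(s$r_v),
                     rhat = fmt_num(s$rhat),
                     delta1 = fmt_num(s$delta1), delta2 = fmt_num(s$delta2),
                     alpha = fmt_num(s$alpha), D = fmt_num(s$D))
    utils::write.csv(gf, file.path(dir, sprintf("geometry_%03d.csv", k)),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(
    data.frame(t = fmt_num(traj$wall_series$t),
               Cv0 = fmt_num(traj$wall_series$Cv0),
               C1_wall0 = fmt_num(traj$wall_series$C1_wall0)),
    file.path(dir, "wall_series.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Re-load a persisted trajectory
#'
#' @param dir Directory written by [write_trajectory()].
#' @return A `cord_trajectory`.
#' @export
read_trajectory <- function(dir) {
  p <- load_config(file.path(dir, "config.yaml"))
  times <- as.numeric(readLines(file.path(dir, "times.csv"))[-1])
  files <- sort(list.files(dir, pattern = "^snapshot_\\d+\\.csv$"))
  snapshots <- lapply(seq_along(files), function(k) {
    df <- utils::read.csv(file.path(dir, sprintf("snapshot_%03d.csv", k)),
                          colClasses = "numeric")
    vf <- utils::read.csv(file.path(dir, sprintf("vessel_%03d.csv", k)),
                          colClasses = "numeric")
    gf <- utils::read.csv(file.path(dir, sprintf("geometry_%03d.csv", k)),
                          colClasses = "numeric")
    r <- sort(unique(df$r)); z <- sort(unique(df$z))
    shape <- function(v) matrix(v, length(r), length(z))
    o <- order(match(df$z, z), match(df$r, r))
    list(t = gf$t, r = r, z = z,
         C1 = shape(df$C1[o]), C2 = shape(df$C2[o]), C3 = shape(df$C3[o]),
         r_v = gf$r_v, rhat = gf$rhat,
         delta1 = gf$delta1, delta2 = gf$delta2, alpha = gf$alpha, D = gf$D,
         Cv = vf$Cv, lambda = vf$lambda, Qleak = vf$Qleak)
  })
  ws <- utils::read.csv(file.path(dir, "wall_series.csv"),
                        colClasses = "numeric")
  structure(list(times = times, snapshots = snapshots,
                 wall_series = tibble::as_tibble(ws),
                 params = p, stats = list()),
            class = "cord_trajectory")
}
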