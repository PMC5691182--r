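# Serialization shared by all modules: CSV artifacts with stable column
# order and 17 significant digits, and schema-versioned JSON reports.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

write_csv17 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' Columns: `t`, one column per state component (split into `.re`/`.im`
#' when complex), `regime`, `segment`. Floats are written with 17
#' significant digits so a round trip is bit-faithful.
#'
#' @param traj A `blowup_trajectory`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  write_csv17(as.data.frame(traj), path)
}

#' Write a trajectory's event log to JSON
#'
#' Switch times, fitted powers and blow-up time estimates, schema-versioned.
#'
#' @param traj A `blowup_trajectory`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_events_json <- function(traj, path) {
  jsonlite::write_json(
    list(schema = "blowthrough/events/1", events = traj$events,
         crossings = crossing_times(traj)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a crossing locus to CSV
#'
#' @param locus Data frame `t, x_left, x_right` (from a `pde_run`).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_locus_csv <- function(locus, path) {
  write_csv17(locus, path)
}

#' Write PDE snapshots to CSV
#'
#' Long format: `t, x, value, representation` where `value` is the stored
#' variable (`w` on regular nodes, `v` in buffers).
#'
#' @param run A `pde_run`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_snapshots_csv <- function(run, path) {
  x <- run$config$grid$x
  df <- do.call(rbind, lapply(run$snapshots, function(s)
    data.frame(t = s$t, x = x, value = s$vals,
               representation = ifelse(s$kinds == 1L, "v", "w"))))
  write_csv17(df, path)
}

#' Write a PDE detection report to JSON
#'
#' @param run A `pde_run`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_report_json <- function(run, path) {
  jsonlite::write_json(
    list(schema = "blowthrough/pde-report/1",
         N = run$config$N, dt = run$config$dt, t_end = run$config$t_end,
         r = run$config$r, W_max = run$config$policy$W_max,
         p_hat = run$detection$p_hat, alpha = run$detection$alpha,
         fit_r2 = run$detection$fit_r2,
         t_first_touch = run$t_first_touch,
         max_regions = max(run$topology$regions)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
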