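#' Define a power lookup-table grid
#'
#' Describes a (series length x effect size) grid of Monte Carlo power
#' estimates at a fixed AR(1) autocorrelation and innovation SD, the
#' design used for quick-reference ITS power tables: intercept 0,
#' intervention at the series midpoint `k = floor(t / 2)`, no covariate,
#' pulse duration fixed at 1, and — for change-in-trend tables — a
#' zero-slope baseline deterministic trend included as a time regressor.
#'
#' @param times Strictly increasing integer vector of series lengths,
#'   minimum 20 (shorter series give non-stationary autocorrelation
#'   estimates).
#' @param effects Strictly increasing vector of effect sizes.
#' @param intervention_kind `"step"`, `"pulse"` or `"trend_change"`.
#' @param ar1 AR(1) coefficient of the error model, in (-1, 1).
#' @param noise_sd Innovation standard deviation.
#' @param n_sims Monte Carlo replicates per cell.
#' @param seed Master seed; per-cell seeds are derived by hashing
#'   `(seed, t, effect)` so cells are independent and order-invariant.
#' @return An object of class `"its_lookup_grid"`.
#' @examples
#' lookup_grid(times = c(40, 60), effects = c(1, 2), n_sims = 200)
#' @export
lookup_grid <- function(times, effects,
                        intervention_kind = c("step", "pulse", "trend_change"),
                        ar1 = 0.5, noise_sd = 1, n_sims = 1000L,
                        seed = 123L) {
  intervention_kind <- match.arg(intervention_kind)
  if (length(times) == 0L || length(effects) == 0L)
    stop("`times` and `effects` must be nonempty", call. = FALSE)
  stopifnot(is.numeric(times), all(times == round(times)),
            is.numeric(effects))
  if (is.unsorted(times, strictly = TRUE) ||
      is.unsorted(effects, strictly = TRUE))
    stop("`times` and `effects` must be strictly increasing", call. = FALSE)
  if (min(times) < 20)
    stop("`times` must be >= 20: shorter series give unstable ",
         "autocorrelation estimates", call. = FALSE)
  structure(list(times = as.integer(times), effects = as.numeric(effects),
                 intervention_kind = intervention_kind, ar1 = ar1,
                 noise_sd = noise_sd, n_sims = as.integer(n_sims),
                 seed = as.integer(seed)),
            class = "its_lookup_grid")
}

# deterministic per-cell seed from (master, t, effect); plain 32-bit-safe
# integer hash so the grid can be filled in any order
cell_seed <- function(master, t, effect) {
  m <- 2147483629
  h <- (abs(as.double(master)) %% m)
  h <- (h * 31 + as.double(t)) %% m
  h <- (h * 31 + abs(round(effect * 1e6)) %% m) %% m
  as.integer(h + 1)
}

# scenario for one lookup cell
cell_scenario <- function(grid, t, effect) {
  its_scenario(
    t = t, k = floor(t / 2), b0 = 0, b1_effect = effect,
    intervention_type = grid$intervention_kind,
    pulse_duration = 1L,
    include_trend = grid$intervention_kind == "trend_change",
    b3_trend = 0,
    trend_model_method = if (grid$intervention_kind == "trend_change")
      "xreg" else "none",
    errormodel = error_model(ar = grid$ar1, noise_sd = grid$noise_sd),
    n_sims = grid$n_sims,
    seed = cell_seed(grid$seed, t, effect))
}

#' Generate a power lookup table
#'
#' Runs [estimate_power()] for every cell of the grid.  Cells are
#' independent simulations with per-cell derived seeds, so the table can
#' be regenerated cell-by-cell (or in parallel) with identical results.
#'
#' @param grid A [lookup_grid()].
#' @return An object of class `"its_lookup"`: the `grid` plus `power` and
#'   `mc_se` matrices (rows = series lengths, columns = effect sizes) and
#'   an `n_failed` matrix of non-converged replicate counts.
#' @examples
#' \donttest{
#' tab <- generate_lookup_table(
#'   lookup_grid(times = c(40, 60), effects = c(1, 2), n_sims = 200))
#' tab
#' }
#' @export
generate_lookup_table <- function(grid) {
  stopifnot(inherits(grid, "its_lookup_grid"))
  nt <- length(grid$times); ne <- length(grid$effects)
  dn <- list(time = as.character(grid$times),
             effect = format(grid$effects, trim = TRUE))
  power <- mc_se <- matrix(NA_real_, nt, ne, dimnames = dn)
  n_failed <- matrix(NA_integer_, nt, ne, dimnames = dn)
  for (i in seq_len(nt)) {
    for (j in seq_len(ne)) {
      est <- estimate_power(cell_scenario(grid, grid$times[i],
                                          grid$effects[j]))
      power[i, j] <- est$power
      mc_se[i, j] <- est$mc_se
      n_failed[i, j] <- est$n_failed
    }
  }
  structure(list(grid = grid, power = power, mc_se = mc_se,
                 n_failed = n_failed),
            class = "its_lookup")
}

#' @export
print.its_lookup <- function(x, ...) {
  g <- x$grid
  cat(sprintf(
    "Power lookup table: %s intervention, AR(1) = %g, noise sd = %g, %d sims/cell\n",
    g$intervention_kind, g$ar1, g$noise_sd, g$n_sims))
  print(round(x$power, 2))
  invisible(x)
}

#' @export
as.data.frame.its_lookup <- function(x, ...) {
  g <- x$grid
  data.frame(time = rep(g$times, times = length(g$effects)),
             effect = rep(g$effects, each = length(g$times)),
             power = as.vector(x$power),
             mc_se = as.vector(x$mc_se),
             n_failed = as.vector(x$n_failed))
}

#' Write / read a lookup table as CSV
#'
#' `write_lookup_csv()` serialises the table losslessly: commented
#' header lines record the grid metadata (format version, intervention
#' kind, AR(1), noise SD, replicates, master seed) followed by tidy
#' long-format rows `time, effect, power, mc_se, n_failed`.
#' `read_lookup_csv()` reconstructs the `"its_lookup"` object exactly.
#' `write_lookup_wide_csv()` additionally writes the printed-table
#' layout: one row per series length, one column per effect size, power
#' formatted to two decimals.
#'
#' @param x An `"its_lookup"` object.
#' @param path Output / input file path.
#' @return `write_*` return `path` invisibly; `read_lookup_csv()` returns
#'   the reconstructed `"its_lookup"`.
#' @export
write_lookup_csv <- function(x, path) {
  stopifnot(inherits(x, "its_lookup"))
  g <- x$grid
  header <- c(
    "# itspower lookup table v1",
    sprintf("# intervention_kind=%s", g$intervention_kind),
    sprintf("# ar1=%.17g", g$ar1),
    sprintf("# noise_sd=%.17g", g$noise_sd),
    sprintf("# n_sims=%d", g$n_sims),
    sprintf("# seed=%d", g$seed))
  df <- as.data.frame(x)
  # %.17g round-trips IEEE doubles exactly
  for (col in c("effect", "power", "mc_se"))
    df[[col]] <- sprintf("%.17g", df[[col]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lookup_csv
#' @export
read_lookup_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1] != "# itspower lookup table v1")
    stop(sprintf("%s, line 1: not an itspower lookup table (bad header)",
                 path), call. = FALSE)
  hdr <- grep("^# ", lines)
  meta <- list()
  for (i in hdr[-1]) {
    kv <- strsplit(sub("^# ", "", lines[i]), "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop(sprintf("%s, line %d: malformed metadata line '%s'",
                   path, i, lines[i]), call. = FALSE)
    meta[[kv[1]]] <- kv[2]
  }
  need <- c("intervention_kind", "ar1", "noise_sd", "n_sims", "seed")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    stop(sprintf("%s: missing metadata field(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  body <- utils::read.csv(text = lines[-hdr])
  need_cols <- c("time", "effect", "power", "mc_se", "n_failed")
  if (!all(need_cols %in% names(body)))
    stop(sprintf("%s, line %d: expected columns %s", path, max(hdr) + 1L,
                 paste(need_cols, collapse = ", ")), call. = FALSE)
  grid <- lookup_grid(times = sort(unique(body$time)),
                      effects = sort(unique(body$effect)),
                      intervention_kind = meta$intervention_kind,
                      ar1 = as.numeric(meta$ar1),
                      noise_sd = as.numeric(meta$noise_sd),
                      n_sims = as.integer(meta$n_sims),
                      seed = as.integer(meta$seed))
  nt <- length(grid$times); ne <- length(grid$effects)
  if (nrow(body) != nt * ne)
    stop(sprintf("%s: expected %d rows (complete grid), found %d", path,
                 nt * ne, nrow(body)), call. = FALSE)
  dn <- list(time = as.character(grid$times),
             effect = format(grid$effects, trim = TRUE))
  power <- mc_se <- matrix(NA_real_, nt, ne, dimnames = dn)
  n_failed <- matrix(NA_integer_, nt, ne, dimnames = dn)
  ri <- match(body$time, grid$times)
  ci <- match(body$effect, grid$effects)
  power[cbind(ri, ci)] <- body$power
  mc_se[cbind(ri, ci)] <- body$mc_se
  n_failed[cbind(ri, ci)] <- body$n_failed
  structure(list(grid = grid, power = power, mc_se = mc_se,
                 n_failed = n_failed),
            class = "its_lookup")
}

#' @rdname write_lookup_csv
#' @export
write_lookup_wide_csv <- function(x, path) {
  stopifnot(inherits(x, "its_lookup"))
  wide <- data.frame(time = x$grid$times,
                     matrix(sprintf("%.2f", x$power), nrow(x$power)),
                     check.names = FALSE)
  names(wide)[-1] <- colnames(x$power)
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Flag lookup cells that break power monotonicity
#'
#' For step-change tables power should be non-decreasing along both the
#' effect-size and series-length axes up to Monte Carlo error.  This
#' helper flags cells whose power falls more than `slack` Monte Carlo
#' standard errors below the maximum to their left (same row) or above
#' (same column): useful when vetting regenerated tables against printed
#' ones whose layout carries typesetting artifacts.
#'
#' @param x An `"its_lookup"` object.
#' @param slack Number of combined Monte Carlo standard errors tolerated.
#' @return Data frame of flagged cells (possibly empty) with columns
#'   `time`, `effect`, `power` and `expected_at_least`.
#' @export
flag_nonmonotone_cells <- function(x, slack = 3) {
  stopifnot(inherits(x, "its_lookup"))
  out <- data.frame(time = integer(0), effect = numeric(0),
                    power = numeric(0), expected_at_least = numeric(0))
  p <- x$power; se <- x$mc_se
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    prior <- c(if (j > 1) p[i, seq_len(j - 1)],
               if (i > 1) p[seq_len(i - 1), j])
    if (length(prior) == 0L) next
    bound <- max(prior) - slack * sqrt(max(se[i, j])^2 + max(se)^2)
    if (p[i, j] < bound)
      out <- rbind(out, data.frame(
        time = x$grid$times[i], effect = x$grid$effects[j],
        power = p[i, j], expected_at_least = bound))
  }
  out
}
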