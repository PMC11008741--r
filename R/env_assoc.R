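#' Simple linear regression of one series on one covariate
#'
#' Ordinary least squares of `y` on `x` (via [stats::lm()]) with
#' pairwise-complete observations: pairs where either value is missing are
#' dropped before fitting. Reports slope, intercept, R-squared and the
#' two-sided p-value of the F test on 1 and n-2 degrees of freedom
#' (equivalent to the t test on the slope).
#'
#' @param y Numeric response series.
#' @param x Numeric covariate series, same length.
#' @return A list of class `regression_result` with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
ols_fit <- function(y, x) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0) stop("covariate is constant; slope undefined")
  if (sd(y) == 0) stop("response is constant; R-squared undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- stats::pf(fstat[["value"]], fstat[["numdf"]], fstat[["dendf"]],
                 lower.tail = FALSE)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared, p_value = p, n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("slope %.4g, intercept %.4g, R^2 = %.3f, p = %.3g (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Screen lineage abundances against environmental covariates
#'
#' Fits one simple linear regression per (lineage, covariate) pair: the
#' lineage's per-timepoint relative abundance (from [aggregate_lineage()])
#' against the covariate, matched on shared timepoints with
#' pairwise-complete observations. Failed fits (absent lineage giving a
#' constant zero series, too few pairs) are reported as rows with missing
#' estimates and a reason rather than errors. No multiple-testing correction
#' is applied by default — each fit's raw p-value is reported, with a
#' significance flag at `p_threshold` — but a Benjamini-Hochberg column can
#' be requested.
#'
#' @param asv An `asv_table`.
#' @param env An `env_table` sharing at least 3 timepoints with `asv`.
#' @param lineages Character vector of lineage names; names of the vector
#'   give the taxonomy rank of each entry (e.g.
#'   `c(phylum = "Desulfobacterota", genus = "Nitzschia")`), unnamed entries
#'   use `rank`.
#' @param covariates Environmental column names, default
#'   `c("secchi_depth", "wind_speed_max", "water_level")`.
#' @param rank Default rank for unnamed lineages, `"phylum"`.
#' @param p_threshold Significance reporting level, default 0.01.
#' @param lag Shift covariates by this many sampling steps relative to the
#'   abundance series (positive = covariate leads), default 0.
#' @param bh Add a BH-adjusted p-value column, default `FALSE`.
#' @return Data frame with one row per (lineage, covariate): `lineage`,
#'   `rank`, `covariate`, `slope`, `intercept`, `r_squared`, `p_value`, `n`,
#'   `significant`, `reason` (non-`NA` only for failed fits).
#' @export
assoc_screen <- function(asv, env, lineages,
                         covariates = c("secchi_depth", "wind_speed_max",
                                        "water_level"),
                         rank = "phylum", p_threshold = 0.01, lag = 0L,
                         bh = FALSE) {
  stopifnot(inherits(asv, "asv_table"), inherits(env, "env_table"))
  bad <- setdiff(covariates, names(env))
  if (length(bad) > 0L) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  ranks <- if (is.null(names(lineages))) rep(rank, length(lineages)) else
    ifelse(names(lineages) == "", rank, names(lineages))
  shared <- intersect(timepoints(asv), env$timepoint)
  if (length(shared) < 3L) stop("fewer than 3 shared timepoints")

  rows <- list()
  for (i in seq_along(lineages)) {
    agg <- suppressWarnings(aggregate_lineage(asv, ranks[i], lineages[[i]]))
    series <- agg$series[as.character(shared)]
    for (cv in covariates) {
      xcv <- env[[cv]][match(shared, env$timepoint)]
      if (lag != 0L) {
        k <- length(xcv)
        xcv <- if (lag > 0L) c(xcv[-seq_len(lag)], rep(NA_real_, lag)) else
          c(rep(NA_real_, -lag), xcv[seq_len(k + lag)])
      }
      res <- tryCatch(ols_fit(series, xcv), error = function(e) conditionMessage(e))
      if (is.character(res)) {
        rows[[length(rows) + 1L]] <- data.frame(
          lineage = lineages[[i]], rank = ranks[i], covariate = cv,
          slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
          p_value = NA_real_, n = NA_integer_, significant = NA,
          reason = res, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          lineage = lineages[[i]], rank = ranks[i], covariate = cv,
          slope = res$slope, intercept = res$intercept,
          r_squared = res$r_squared, p_value = res$p_value, n = res$n,
          significant = res$p_value < p_threshold, reason = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (bh) {
    ok <- !is.na(out$p_value)
    out$p_adj <- NA_real_
    out$p_adj[ok] <- bh_adjust(out$p_value[ok])
  }
  out
}
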