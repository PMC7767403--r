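# Linear interaction energy (LIE) binding free energies and the
# four-system thermodynamic cycle giving the relative binding free energy
# ddG_bind between the wild-type (AT) and substituted (GC) base pair.
#
# Per system, dG_bind = alpha * (<E_vdw>_bound - <E_vdw>_unbound)
#                     + beta  * (<E_el>_bound  - <E_el>_unbound),
# and ddG_bind = dG_bind(GC) - dG_bind(AT); a negative value means the
# transcription factor binds the substituted DNA more strongly.  Entropic
# contributions are implicit in the empirical alpha/beta parametrisation;
# no explicit entropy term is computed.

#' LIE empirical parameters
#'
#' @param alpha weight of the van der Waals term (dimensionless).
#' @param beta weight of the electrostatic term (dimensionless).
#' @return object of class `lie_params`.
#' @export
lie_params <- function(alpha = 0.18, beta = 0.43) {
  if (!is.finite(alpha) || !is.finite(beta))
    stop("alpha and beta must be finite")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "lie_params")
}

#' Mean interaction energies with block-averaged standard errors
#'
#' Arithmetic means of the van der Waals and electrostatic series and their
#' standard errors by block averaging: the series is cut into
#' `block_count` contiguous blocks (trailing remainder dropped) and the
#' standard deviation of the block means, divided by sqrt(block_count),
#' estimates the standard error in the presence of autocorrelation.
#'
#' @param series an [energy_series].
#' @param block_count number of blocks (2 <= block_count <= length).
#' @return object of class `mean_energies`: `variant`, `environment`,
#'   `mean_vdw`, `mean_el`, `se_vdw`, `se_el` (kcal/mol), `n_samples`.
#' @export
mean_interaction_energies <- function(series, block_count = 10L) {
  stopifnot(inherits(series, "energy_series"))
  n <- length(series$e_vdw)
  block_count <- as.integer(block_count)
  if (block_count < 2L) stop("block_count must be >= 2")
  if (n < block_count)
    stop("series has ", n, " samples, fewer than ", block_count, " blocks")
  block_se <- function(x) {
    m <- n %/% block_count
    bm <- colMeans(matrix(x[seq_len(m * block_count)], nrow = m))
    stats::sd(bm) / sqrt(block_count)
  }
  mean_energies(series$variant, series$environment,
                mean_vdw = mean(series$e_vdw), mean_el = mean(series$e_el),
                se_vdw = block_se(series$e_vdw),
                se_el = block_se(series$e_el), n_samples = n)
}

#' Construct a mean-energy record for one system
#'
#' @param variant `"AT"` or `"GC"`.
#' @param environment `"Complex"` or `"DNA"`.
#' @param mean_vdw,mean_el mean interaction energies, kcal/mol.
#' @param se_vdw,se_el standard errors (>= 0), kcal/mol.
#' @param n_samples number of samples behind the means.
#' @return object of class `mean_energies`.
#' @export
mean_energies <- function(variant, environment, mean_vdw, mean_el,
                          se_vdw = 0, se_el = 0, n_samples = 1L) {
  variant <- match.arg(variant, c("AT", "GC"))
  environment <- match.arg(environment, c("Complex", "DNA"))
  if (se_vdw < 0 || se_el < 0) stop("standard errors must be >= 0")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  structure(list(variant = variant, environment = environment,
                 mean_vdw = as.numeric(mean_vdw),
                 mean_el = as.numeric(mean_el),
                 se_vdw = as.numeric(se_vdw), se_el = as.numeric(se_el),
                 n_samples = as.integer(n_samples)),
            class = "mean_energies")
}

#' @export
print.mean_energies <- function(x, ...) {
  cat(sprintf(
    "<mean_energies> %s/%s: <E_vdw> %.3f +/- %.3f, <E_el> %.3f +/- %.3f kcal/mol (n=%d)\n",
    x$variant, x$environment, x$mean_vdw, x$se_vdw, x$mean_el, x$se_el,
    x$n_samples))
  invisible(x)
}

#' LIE binding free energy of one variant
#'
#' @param bound [mean_energies] of the protein-bound state
#'   (`environment == "Complex"`).
#' @param unbound [mean_energies] of the free-DNA state
#'   (`environment == "DNA"`), same variant.
#' @param params a [lie_params].
#' @return list with `dg` (kcal/mol), `vdw_component`, `el_component`,
#'   `se` (propagated), `variant`.
#' @export
lie_delta_g <- function(bound, unbound, params = lie_params()) {
  stopifnot(inherits(bound, "mean_energies"),
            inherits(unbound, "mean_energies"))
  if (bound$environment != "Complex" || unbound$environment != "DNA")
    stop("bound must be a Complex record and unbound a DNA record")
  if (bound$variant != unbound$variant)
    stop("bound (", bound$variant, ") and unbound (", unbound$variant,
         ") records belong to different variants")
  vdw <- params$alpha * (bound$mean_vdw - unbound$mean_vdw)
  el <- params$beta * (bound$mean_el - unbound$mean_el)
  se <- sqrt(params$alpha^2 * (bound$se_vdw^2 + unbound$se_vdw^2) +
               params$beta^2 * (bound$se_el^2 + unbound$se_el^2))
  list(dg = vdw + el, vdw_component = vdw, el_component = el, se = se,
       variant = bound$variant)
}

find_cell <- function(cells, variant, environment) {
  hit <- Filter(function(c) c$variant == variant &&
                  c$environment == environment, cells)
  if (length(hit) != 1L)
    stop("incomplete thermodynamic cycle: need exactly one mean-energy ",
         "record for (", variant, ", ", environment, "), found ",
         length(hit))
  hit[[1]]
}

#' Relative binding free energy from the four-system cycle
#'
#' Combines the four mean-energy records {AT, GC} x {Complex, DNA} into
#' ddG_bind = dG_bind(GC) - dG_bind(AT), with the electrostatic
#' (beta-weighted) and van der Waals (alpha-weighted) components reported
#' separately and the uncertainty propagated as the root sum of squares of
#' the four scaled standard errors.
#'
#' @param cells list of four [mean_energies], one per (variant,
#'   environment).
#' @param params a [lie_params].
#' @return object of class `lie_result`; see [pool_runs()] for the pooled
#'   multi-run variant.
#' @export
ddg_bind <- function(cells, params = lie_params()) {
  at <- lie_delta_g(find_cell(cells, "AT", "Complex"),
                    find_cell(cells, "AT", "DNA"), params)
  gc <- lie_delta_g(find_cell(cells, "GC", "Complex"),
                    find_cell(cells, "GC", "DNA"), params)
  new_lie_result(dg_bind_at = at$dg, dg_bind_gc = gc$dg,
                 ddg = gc$dg - at$dg,
                 ddg_el_component = gc$el_component - at$el_component,
                 ddg_vdw_component = gc$vdw_component - at$vdw_component,
                 se_ddg = sqrt(at$se^2 + gc$se^2),
                 params = params, per_run = NULL, n_runs = 1L)
}

new_lie_result <- function(dg_bind_at, dg_bind_gc, ddg, ddg_el_component,
                           ddg_vdw_component, se_ddg, params, per_run,
                           n_runs) {
  structure(list(dg_bind_at = dg_bind_at, dg_bind_gc = dg_bind_gc,
                 ddg = ddg, ddg_el_component = ddg_el_component,
                 ddg_vdw_component = ddg_vdw_component, se_ddg = se_ddg,
                 params = params, per_run = per_run, n_runs = n_runs),
            class = "lie_result")
}

#' Closure of the four-state thermodynamic cycle
#'
#' Evaluates dG_bind(AT) + dG(AT->GC, Complex) - dG_bind(GC)
#' - dG(AT->GC, DNA), which is identically zero for any four mean-energy
#' records: the alchemical legs are defined by the same linear energy
#' differences as the binding legs.
#'
#' @param cells list of four [mean_energies].
#' @param params a [lie_params].
#' @return the closure value, kcal/mol (0 up to round-off).
#' @export
cycle_closure <- function(cells, params = lie_params()) {
  leg <- function(environment) {
    gcc <- find_cell(cells, "GC", environment)
    atc <- find_cell(cells, "AT", environment)
    params$alpha * (gcc$mean_vdw - atc$mean_vdw) +
      params$beta * (gcc$mean_el - atc$mean_el)
  }
  r <- ddg_bind(cells, params)
  r$dg_bind_at + leg("Complex") - r$dg_bind_gc - leg("DNA")
}

#' Pool per-run LIE results into a replicate estimate
#'
#' The pooled ddG is the unweighted mean of the per-run values (the runs
#' are equal-length replicates) and its standard error is the sample
#' standard deviation of the per-run values divided by sqrt(n_runs).
#'
#' @param per_run list of single-run [lie_result] objects (>= 2).
#' @return a pooled `lie_result` whose `per_run` field tabulates the runs.
#' @export
pool_runs <- function(per_run) {
  if (inherits(per_run, "lie_result")) per_run <- list(per_run)
  if (length(per_run) < 2L)
    stop("pooling needs at least 2 runs; report the single run directly")
  grab <- function(f) vapply(per_run, `[[`, numeric(1), f)
  tab <- data.frame(run = seq_along(per_run), ddg = grab("ddg"),
                    el_component = grab("ddg_el_component"),
                    vdw_component = grab("ddg_vdw_component"),
                    dg_bind_at = grab("dg_bind_at"),
                    dg_bind_gc = grab("dg_bind_gc"),
                    se_ddg = grab("se_ddg"))
  new_lie_result(dg_bind_at = mean(tab$dg_bind_at),
                 dg_bind_gc = mean(tab$dg_bind_gc),
                 ddg = mean(tab$ddg),
                 ddg_el_component = mean(tab$el_component),
                 ddg_vdw_component = mean(tab$vdw_component),
                 se_ddg = stats::sd(tab$ddg) / sqrt(nrow(tab)),
                 params = per_run[[1]]$params, per_run = tab,
                 n_runs = nrow(tab))
}

#' Fit the relative binding free energy from replicate energy series
#'
#' The package's central estimator: takes the raw per-run interaction
#' energy series of the four systems, computes per-run mean energies with
#' block-averaged errors, per-run ddG_bind values through the
#' thermodynamic cycle, and pools the replicates.
#'
#' @param energies either a list of runs -- each run itself a list of four
#'   [energy_series] covering {AT, GC} x {Complex, DNA} -- or, for a single
#'   run, a flat list of four series.
#' @param params a [lie_params].
#' @param block_count blocks for the per-run standard errors.
#' @return a pooled [`lie_result`][ddg_bind] (single-run if only one run
#'   given), supporting `print()`, `summary()`, `coef()` and `confint()`.
#' @export
lie_ddg <- function(energies, params = lie_params(), block_count = 10L) {
  if (length(energies) && inherits(energies[[1]], "energy_series"))
    energies <- list(energies)
  if (!length(energies)) stop("no energy series supplied")
  per_run <- lapply(energies, function(run) {
    cells <- lapply(run, mean_interaction_energies,
                    block_count = block_count)
    ddg_bind(cells, params)
  })
  if (length(per_run) == 1L) per_run[[1]] else pool_runs(per_run)
}

#' @export
print.lie_result <- function(x, digits = 3, ...) {
  cat("Relative LIE binding free energy (GC - AT)\n")
  cat(sprintf("  ddG_bind = %+.*f +/- %.*f kcal/mol (%s)\n", digits, x$ddg,
              digits, x$se_ddg,
              if (x$n_runs > 1L) paste(x$n_runs, "pooled runs")
              else "single run"))
  cat(sprintf("  components: electrostatic %+.*f, van der Waals %+.*f\n",
              digits, x$ddg_el_component, digits, x$ddg_vdw_component))
  cat(sprintf("  dG_bind: AT %+.*f, GC %+.*f (alpha=%g, beta=%g)\n",
              digits, x$dg_bind_at, digits, x$dg_bind_gc, x$params$alpha,
              x$params$beta))
  invisible(x)
}

#' @export
summary.lie_result <- function(object, ...) {
  structure(list(result = object), class = "summary.lie_result")
}

#' @export
print.summary.lie_result <- function(x, ...) {
  print(x$result)
  if (!is.null(x$result$per_run)) {
    cat("\nPer-run values (kcal/mol):\n")
    print(x$result$per_run, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.lie_result <- function(object, ...) {
  c(ddg = object$ddg, ddg_el = object$ddg_el_component,
    ddg_vdw = object$ddg_vdw_component)
}

#' @export
confint.lie_result <- function(object, parm = "ddg", level = 0.95, ...) {
  q <- if (object$n_runs > 1L)
    stats::qt(1 - (1 - level) / 2, df = object$n_runs - 1L)
  else stats::qnorm(1 - (1 - level) / 2)
  ci <- matrix(c(object$ddg - q * object$se_ddg,
                 object$ddg + q * object$se_ddg), 1, 2,
               dimnames = list("ddg", sprintf("%.1f %%",
                                              100 * c((1 - level) / 2,
                                                      1 - (1 - level) / 2))))
  ci
}
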