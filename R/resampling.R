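# Shared bootstrap / permutation engine with reproducible seeding.

#' Signal a degenerate resample
#'
#' Statistics passed to [bootstrap()] call this when a replicate cannot be
#' evaluated (e.g. a resampled control group whose mean fitness is zero, which
#' would put a zero in the denominator of the selection coefficient). The
#' engine catches the condition, redraws the replicate and counts it.
#'
#' @param message Description of the degeneracy.
#' @export
degenerate_error <- function(message = "degenerate resample") {
  stop(structure(
    class = c("oppsel_degenerate", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

is_degenerate_condition <- function(e) inherits(e, "oppsel_degenerate")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so library calls never perturb the
#' caller's RNG state. All randomised functions in this package funnel
#' through here, which is what makes whole runs byte-reproducible.
#'
#' @param seed Integer seed (< 2^31).
#' @param code Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive an independent sub-seed from a master seed and a label
#'
#' A master seed spawns one deterministic substream per analysis cell, so
#' adding or reordering cells never perturbs the draws of the others. The
#' label is hashed with a small polynomial rolling hash and mixed with the
#' master seed modulo 2^31 - 1 (always a valid, positive R integer seed).
#'
#' @param master Integer master seed.
#' @param key Character label of the analysis cell (any string).
#' @return Integer in `[1, 2^31 - 2]`.
#' @examples
#' spawn_seed(42, "wheat/male/none")
#' @export
spawn_seed <- function(master, key) {
  stopifnot(length(master) == 1, is.finite(master), length(key) == 1)
  m <- 2147483647 # 2^31 - 1, prime
  h <- (as.double(master) %% m)
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 131 + ch) %% m # 131 * m < 2^53: exact in doubles
  }
  as.integer(h %% (m - 2) + 1)
}

as_group_list <- function(data) {
  if (is.list(data) && !is.data.frame(data)) data else list(data)
}

resample_group <- function(g) {
  if (is.data.frame(g)) {
    g[sample.int(nrow(g), nrow(g), replace = TRUE), , drop = FALSE]
  } else {
    g[sample.int(length(g), length(g), replace = TRUE)]
  }
}

#' Percentile confidence interval
#'
#' Empirical quantiles of the replicate distribution using R's default
#' type-7 (linear interpolation) definition; implementations of the
#' percentile bootstrap differ in this convention, so it is pinned here.
#'
#' @param replicates Numeric vector or matrix (replicates x terms).
#' @param level Coverage level in (0, 1).
#' @return Named vector `c(low, high)`, or a 2-row matrix for matrix input.
#' @export
percentile_ci <- function(replicates, level = 0.95) {
  stopifnot(level > 0, level < 1)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  if (is.matrix(replicates)) {
    apply(replicates, 2, stats::quantile, probs = probs, names = FALSE,
          type = 7)
  } else {
    ci <- stats::quantile(replicates, probs = probs, names = FALSE, type = 7)
    c(low = ci[1], high = ci[2])
  }
}

#' Nonparametric bootstrap over one or more groups
#'
#' Each group is resampled independently with replacement at its own size
#' (the design of the assays fixes group sizes, so stratified resampling is
#' the correct analogue of repeating the experiment). The statistic may
#' return a scalar or a named vector; percentile intervals are computed
#' per component.
#'
#' Replicates in which the statistic signals [degenerate_error()] are
#' redrawn and counted; if more than 1% of requested replicates were
#' degenerate a warning is attached to the result (and emitted).
#'
#' @param data A vector/data.frame (single group) or a list of them.
#' @param statistic Function taking the list of groups, returning numeric.
#' @param n Number of bootstrap replicates (default 10000, the convention
#'   for these assays). `n = 0` returns the point estimate only.
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; required for reproducibility.
#' @param max_redraw Maximum consecutive redraws of a single replicate.
#' @return Object of class `resample_result`: list with `point`,
#'   `replicates` (matrix n x k), `boot_mean`, `ci` (2 x k matrix, rows
#'   `low`/`high`), `n_resamples`, `n_degenerate`, `level`, `seed`.
#' @examples
#' r <- bootstrap(rnorm(30), function(g) mean(g[[1]]), n = 200, seed = 1)
#' r$ci
#' @export
bootstrap <- function(data, statistic, n = 10000, level = 0.95, seed = NULL,
                      max_redraw = 1000L) {
  groups <- as_group_list(data)
  sizes <- vapply(groups, function(g) {
    if (is.data.frame(g)) nrow(g) else length(g)
  }, integer(1))
  if (any(sizes == 0)) stop("bootstrap: every group must be nonempty")
  stopifnot(level > 0, level < 1, n >= 0)

  point <- statistic(groups)
  k <- length(point)
  nm <- names(point)

  if (n == 0) {
    out <- list(point = point, replicates = NULL, boot_mean = NULL, ci = NULL,
                n_resamples = 0L, n_degenerate = 0L, level = level,
                seed = seed)
    class(out) <- "resample_result"
    return(out)
  }

  reps <- matrix(NA_real_, nrow = n, ncol = k, dimnames = list(NULL, nm))
  n_degenerate <- 0L
  with_seed(seed, {
    for (b in seq_len(n)) {
      val <- NULL
      for (try in seq_len(max_redraw)) {
        val <- tryCatch(statistic(lapply(groups, resample_group)),
                        oppsel_degenerate = function(e) NULL)
        if (!is.null(val)) break
        n_degenerate <- n_degenerate + 1L
      }
      if (is.null(val)) {
        stop("bootstrap: replicate still degenerate after ", max_redraw,
             " redraws")
      }
      reps[b, ] <- val
    }
  })

  out <- list(
    point = point,
    replicates = if (k == 1) drop(reps) else reps,
    boot_mean = colMeans(reps),
    ci = {
      ci <- percentile_ci(reps, level)
      rownames(ci) <- c("low", "high")
      ci
    },
    n_resamples = as.integer(n),
    n_degenerate = n_degenerate,
    level = level,
    seed = seed
  )
  if (n_degenerate > 0.01 * n) {
    warning(sprintf("bootstrap: %d degenerate replicates redrawn (> 1%% of %d)",
                    n_degenerate, n))
    out$degenerate_warning <- TRUE
  }
  class(out) <- "resample_result"
  out
}

#' @export
print.resample_result <- function(x, ...) {
  cat("Bootstrap resampling result\n")
  cat("  point:     ", paste(signif(x$point, 5), collapse = " "), "\n")
  if (!is.null(x$boot_mean)) {
    cat("  boot mean: ", paste(signif(x$boot_mean, 5), collapse = " "), "\n")
    ci <- if (is.matrix(x$ci)) x$ci else matrix(x$ci, ncol = 1)
    cat(sprintf("  %g%% CI:   [%s] - [%s]\n", 100 * x$level,
                paste(signif(ci[1, ], 5), collapse = " "),
                paste(signif(ci[2, ], 5), collapse = " ")))
  }
  cat("  replicates:", x$n_resamples, " degenerate redraws:",
      x$n_degenerate, "\n")
  invisible(x)
}

shuffle_within_strata <- function(n_total, strata) {
  perm <- integer(n_total)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    perm[idx] <- idx[sample.int(length(idx))]
  }
  perm
}

#' Two-group permutation test
#'
#' Pools the two groups, reshuffles labels preserving group sizes (within
#' strata if given), and recomputes the statistic. The p-value uses the
#' add-one smoothing p = (1 + #extreme) / (n + 1), which guarantees p > 0
#' and makes the null distribution super-uniform at worst.
#'
#' @param a,b Vectors or data.frames; rows are exchangeable units.
#' @param statistic Function of (a, b) returning a scalar.
#' @param n Number of permutations (default 10000).
#' @param alternative "two_sided" (on |statistic|), "greater" or "less".
#' @param seed Integer seed.
#' @param strata Optional vector of stratum labels, length
#'   `n_a + n_b` (a first), restricting label shuffles to within-stratum.
#' @return List with `p`, `observed`, `permuted` (vector of n values),
#'   `n_permutations`, `alternative`, `seed`.
#' @examples
#' permutation_test(rnorm(10), rnorm(10) + 2,
#'                  function(x, y) mean(y) - mean(x), n = 199, seed = 1)$p
#' @export
permutation_test <- function(a, b, statistic, n = 10000,
                             alternative = c("two_sided", "greater", "less"),
                             seed = NULL, strata = NULL) {
  alternative <- match.arg(alternative)
  if (n < 1) stop("permutation_test: n must be >= 1")
  take <- function(x, idx) {
    if (is.data.frame(x)) x[idx, , drop = FALSE] else x[idx]
  }
  na <- if (is.data.frame(a)) nrow(a) else length(a)
  nb <- if (is.data.frame(b)) nrow(b) else length(b)
  if (na == 0 || nb == 0) stop("permutation_test: both groups must be nonempty")
  pooled <- if (is.data.frame(a)) rbind(a, b) else c(a, b)
  if (!is.null(strata)) stopifnot(length(strata) == na + nb)

  observed <- statistic(a, b)
  permuted <- numeric(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      perm <- if (is.null(strata)) {
        sample.int(na + nb)
      } else {
        shuffle_within_strata(na + nb, strata)
      }
      pa <- take(pooled, perm[seq_len(na)])
      pb <- take(pooled, perm[na + seq_len(nb)])
      permuted[i] <- statistic(pa, pb)
    }
  })

  # NA permuted statistics (degenerate pseudo-groups) count as extreme:
  # conservative, keeps p valid.
  cmp <- switch(alternative,
    two_sided = abs(permuted) >= abs(observed),
    greater   = permuted >= observed,
    less      = permuted <= observed
  )
  extreme <- sum(cmp | is.na(cmp))
  list(
    p = (1 + extreme) / (n + 1),
    observed = observed,
    permuted = permuted,
    n_permutations = as.integer(n),
    alternative = alternative,
    seed = seed
  )
}
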