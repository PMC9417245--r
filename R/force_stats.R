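# Rupture-force statistics: contour-length normalization, Gaussian
# mixture peak fitting (EM + BIC), peak patterns, two-sample KS
# comparison, and the candidate-vs-reference validation report.

#' Default contour length for position normalization
#'
#' Fully extended length of the pulled chain used to normalize rupture
#' positions: residues x per-residue contour (0.4 nm/residue, the
#' conventional polypeptide contour increment).
#'
#' @param n_residues chain length (default 41: Cys anchor + 40 residues).
#' @param per_residue contour per residue in nm.
#' @return contour length in nm.
#' @export
default_contour_length <- function(n_residues = 41L, per_residue = 0.4) {
  n_residues * per_residue
}

#' Normalize rupture positions by a contour length
#'
#' @param dataset a [rupture_dataset()] with positions in nm.
#' @param contour_length contour length in nm (> 0).
#' @return a normalized [rupture_dataset()]; events whose normalized
#'   position falls outside `[0, 1]` are dropped from the dataset and
#'   reported via the `n_out_of_range` attribute (never silently clipped).
#' @export
normalize_positions <- function(dataset,
                                contour_length = default_contour_length()) {
  stopifnot(inherits(dataset, "rupture_dataset"))
  if (dataset$normalized) stop("dataset is already normalized")
  if (contour_length <= 0) stop("contour_length must be > 0")
  pos <- dataset$positions / contour_length
  out_of_range <- pos < 0 | pos > 1
  ds <- rupture_dataset(dataset$forces[!out_of_range], pos[!out_of_range],
                        label = dataset$label, normalized = TRUE)
  attr(ds, "n_out_of_range") <- sum(out_of_range)
  ds
}

# ---- 1D Gaussian mixture by EM --------------------------------------

.gmm_em_1d <- function(x, k, seed = 1L, max_iter = 500L, tol = 1e-9) {
  n <- length(x)
  sd_floor <- max(1e-8, 1e-4 * sd(x))
  if (k == 1L) {
    mu <- mean(x); sg <- max(sd(x) * sqrt((n - 1) / n), sd_floor)
    ll <- sum(dnorm(x, mu, sg, log = TRUE))
    return(list(weight = 1, mean = mu, sd = sg, loglik = ll))
  }
  set.seed(as.integer(seed))
  km <- kmeans(x, centers = k, nstart = 10)
  mu <- as.numeric(km$centers)
  sg <- vapply(seq_len(k), function(j) {
    s <- sd(x[km$cluster == j])
    if (!is.finite(s) || s < sd_floor) sd(x) / k else s
  }, numeric(1))
  w <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], sg[j]),
                   numeric(n))
    rs <- rowSums(dens)
    rs[rs == 0] <- .Machine$double.xmin
    ll <- sum(log(rs))
    r <- dens / rs
    nk <- colSums(r)
    w <- nk / n
    mu <- colSums(r * x) / nk
    sg <- sqrt(colSums(r * (outer(x, mu, "-"))^2) / nk)
    sg <- pmax(sg, sd_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(weight = w[ord], mean = mu[ord], sd = sg[ord], loglik = ll)
}

#' Fit Gaussian mixture peaks to a sample
#'
#' Fits 1..`max_components` Gaussian mixtures by EM (kmeans-seeded) and
#' selects the component count by BIC. Deterministic given `seed`.
#'
#' @param x numeric sample (n >= 10, non-degenerate).
#' @param max_components maximum number of mixture components.
#' @param seed seed for the kmeans initialization.
#' @return object of class `gaussian_fit`: data.frame `components`
#'   (weight, mean, sd, sorted by mean), `n_components`, `loglik`, `bic`,
#'   `bic_all`.
#' @export
fit_gaussian_peaks <- function(x, max_components = 3L, seed = 1L) {
  x <- as.numeric(x)
  if (length(x) < 10L) stop("need at least 10 observations")
  if (sd(x) == 0) stop("degenerate sample with zero variance")
  n <- length(x)
  fits <- lapply(seq_len(max_components), function(k) {
    if (k > length(unique(x))) return(NULL)
    .gmm_em_1d(x, k, seed = seed)
  })
  bic <- vapply(seq_along(fits), function(k) {
    if (is.null(fits[[k]])) return(Inf)
    p <- 3 * k - 1
    -2 * fits[[k]]$loglik + p * log(n)
  }, numeric(1))
  best <- which.min(bic)
  f <- fits[[best]]
  structure(list(components = data.frame(weight = f$weight, mean = f$mean,
                                         sd = f$sd),
                 n_components = best, loglik = f$loglik,
                 bic = bic[best], bic_all = bic),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> %d component(s), BIC %.1f\n", x$n_components,
              x$bic))
  print(round(x$components, 4))
  invisible(x)
}

#' Interaction-pattern peaks of normalized rupture positions
#'
#' Mixture fit on the normalized positions; centers are reported sorted
#' ascending with a sequence-region label (N-terminal / central /
#' C-terminal thirds of the pulling coordinate).
#'
#' @param dataset a normalized [rupture_dataset()].
#' @param max_components maximum mixture components (default 3).
#' @param seed initialization seed.
#' @return data.frame with `center`, `weight`, `sd`, `region`.
#' @export
peak_pattern <- function(dataset, max_components = 3L, seed = 1L) {
  stopifnot(inherits(dataset, "rupture_dataset"))
  if (!length(dataset$positions)) stop("empty dataset")
  if (!dataset$normalized) stop("positions must be normalized first")
  fit <- fit_gaussian_peaks(dataset$positions, max_components, seed = seed)
  cmp <- fit$components
  region <- cut(cmp$mean, c(-Inf, 1 / 3, 2 / 3, Inf),
                labels = c("N-terminal", "central", "C-terminal"))
  data.frame(center = cmp$mean, weight = cmp$weight, sd = cmp$sd,
             region = as.character(region))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS via [stats::ks.test()] (exact p for small
#' samples, asymptotic otherwise). Decision "similar" iff `p > alpha`.
#'
#' @param a,b numeric samples (each n >= 5).
#' @param alpha significance level (default 0.05).
#' @param variable label of the compared variable.
#' @return object of class `comparison_report`: `D`, `p_value`,
#'   `similar`, `alpha`, `n_a`, `n_b`, `variable`.
#' @export
ks_compare <- function(a, b, alpha = 0.05, variable = "force") {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 5L || length(b) < 5L) stop("need at least 5 values per sample")
  kt <- suppressWarnings(ks.test(a, b, alternative = "two.sided"))
  structure(list(D = unname(kt$statistic), p_value = kt$p.value,
                 similar = kt$p.value > alpha, alpha = alpha,
                 n_a = length(a), n_b = length(b), variable = variable),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s: D = %.4f, p = %.4g -> %s at alpha = %g\n",
              x$variable, x$D, x$p_value,
              if (x$similar) "similar" else "dissimilar", x$alpha))
  invisible(x)
}

#' Rank candidate rupture datasets against a reference
#'
#' Each candidate is compared with the reference by two-sample KS on the
#' forces and (when position scales agree) on the positions. A candidate
#' is flagged "statistically similar" when every tested variable passes
#' at the Sidak-adjusted per-test level `1 - (1 - alpha)^(1/m)` (so the
#' familywise error over the `m` tests equals `alpha`); set
#' `adjust = "none"` for a plain per-test conjunction. Candidates are
#' ranked by Fisher-combined p (descending).
#'
#' @param candidates list of [rupture_dataset()]s.
#' @param reference a [rupture_dataset()].
#' @param alpha familywise significance level.
#' @param variables which variables enter the decision.
#' @param adjust `"sidak"` (default) or `"none"`.
#' @return object of class `validation_report`: data.frame `table` with
#'   per-candidate KS results, mean/sd summaries, similarity flag and
#'   rank; plus `alpha`, `alpha_each`, `reference_label`.
#' @export
validation_report <- function(candidates, reference, alpha = 0.05,
                              variables = c("force", "position"),
                              adjust = c("sidak", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(length(candidates) >= 1L, inherits(reference, "rupture_dataset"))
  variables <- match.arg(variables, several.ok = TRUE)
  m <- length(variables)
  alpha_each <- if (adjust == "sidak") 1 - (1 - alpha)^(1 / m) else alpha
  rows <- lapply(seq_along(candidates), function(i) {
    cd <- candidates[[i]]
    stopifnot(inherits(cd, "rupture_dataset"))
    kf <- ks_compare(cd$forces, reference$forces, alpha_each, "force")
    kp <- NULL
    if ("position" %in% variables) {
      if (cd$normalized != reference$normalized)
        stop("candidate and reference position scales differ (normalize first)")
      kp <- ks_compare(cd$positions, reference$positions, alpha_each,
                       "position")
    }
    ps <- c(if ("force" %in% variables) kf$p_value,
            if ("position" %in% variables) kp$p_value)
    sim <- all(ps > alpha_each)
    fisher <- -2 * sum(log(pmax(ps, .Machine$double.xmin)))
    combined_p <- pchisq(fisher, df = 2 * length(ps), lower.tail = FALSE)
    data.frame(candidate = if (nzchar(cd$label)) cd$label else paste0("candidate_", i),
               n = length(cd$forces),
               mean_force = mean(cd$forces), sd_force = sd(cd$forces),
               D_force = kf$D, p_force = kf$p_value,
               D_position = if (is.null(kp)) NA_real_ else kp$D,
               p_position = if (is.null(kp)) NA_real_ else kp$p_value,
               combined_p = combined_p, similar = sim)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$combined_p), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, alpha = alpha, alpha_each = alpha_each,
                 variables = variables,
                 reference_label = reference$label),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> vs '%s' (alpha = %g, per-test %g):\n",
              x$reference_label, x$alpha, x$alpha_each))
  print(x$table[, c("rank", "candidate", "n", "mean_force", "p_force",
                    "p_position", "similar")], digits = 4)
  invisible(x)
}
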