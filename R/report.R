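#' Integrin activation index
#'
#' \eqn{AI = (F - F_0)/(F_{max} - F_0)}: activation-specific antibody
#' binding normalized between the inhibitor floor and the
#' activating-antibody ceiling. Invariant under a common affine rescaling
#' of all three fluorescence inputs.
#'
#' @param F mean fluorescence intensity of the activation reporter.
#' @param F0 MFI in the presence of the competitive inhibitor.
#' @param Fmax MFI in the presence of the activating antibody.
#' @return Dimensionless activation index (vectorized over `F`).
#' @export
activation_index <- function(F, F0, Fmax) {
  if (any(Fmax == F0))
    stop("activation index undefined: Fmax equals F0")
  (F - F0) / (Fmax - F0)
}

#' Two-sided Mann-Whitney rank-sum comparison
#'
#' U statistic with midrank tie handling. For small samples (both sizes at
#' most `exact_max`) the two-sided p-value is computed by exhaustive
#' enumeration of all group assignments — exact even under ties; larger
#' samples use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param exact_max largest group size for the exact enumeration path.
#' @return List: `u_statistic` (U of `a` over `b`), `p_value`, `method`.
#' @export
compare_conditions <- function(a, b, exact_max = 8) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample must contain at least 2 values")
  na <- length(a); nb <- length(b)
  comb <- c(a, b)
  rk <- rank(comb)
  u_stat <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (na <= exact_max && nb <= exact_max) {
    idx <- utils::combn(na + nb, na)
    us <- apply(idx, 2, function(i) sum(rk[i])) - na * (na + 1) / 2
    p <- mean(abs(us - mu) >= abs(u_stat - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    n <- na + nb
    ties <- table(comb)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) { p <- 1 } else {
      z <- (abs(u_stat - mu) - 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    method <- "normal approximation with tie correction"
  }
  list(u_statistic = unname(u_stat), p_value = p, method = method)
}

#' Per-condition bundle of scalar readouts
#'
#' @param condition_label unique condition name.
#' @param samples named list of numeric vectors (e.g.
#'   `assembly_rate`, `na_lifetime`, `total_force`).
#' @param n_cells number of cells the readouts came from.
#' @return A `condition_summary` object.
#' @export
condition_summary <- function(condition_label, samples, n_cells = NA_integer_) {
  stopifnot(is.character(condition_label), is.list(samples),
            !is.null(names(samples)), all(nzchar(names(samples))))
  structure(list(condition_label = condition_label, samples = samples,
                 n_cells = n_cells,
                 n_adhesions = max(lengths(samples))),
            class = "condition_summary")
}

significance_stars <- function(p) {
  ifelse(p < 1e-10, "****", ifelse(p < 1e-5, "***",
    ifelse(p < 1e-2, "**", "")))
}

#' Aggregate condition summaries into readout tables and comparisons
#'
#' For every readout present in the summaries: a table of median, quartiles
#' and n per condition, Tukey boxplot statistics, and all pairwise
#' Mann-Whitney comparisons with significance stars at p < 1e-2 (**),
#' 1e-5 (***) and 1e-10 (****). No multiple-testing correction is applied
#' (noted in the footer).
#'
#' @param summaries list of [condition_summary()] objects with unique
#'   labels.
#' @return A `readout_report`: list with `tables`, `comparisons`,
#'   `boxplots`, `footer`.
#' @export
build_report <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  labels <- vapply(summaries, `[[`, "", "condition_label")
  if (anyDuplicated(labels)) stop("condition labels must be unique")
  readouts <- unique(unlist(lapply(summaries, function(s) names(s$samples))))
  tables <- comparisons <- boxplots <- list()
  for (r in readouts) {
    have <- vapply(summaries, function(s) r %in% names(s$samples),
                   logical(1))
    ss <- summaries[have]
    tab <- do.call(rbind, lapply(ss, function(s) {
      v <- s$samples[[r]]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(condition = s$condition_label, n = length(v),
                 q1 = q[1], median = q[2], q3 = q[3])
    }))
    rownames(tab) <- NULL
    tables[[r]] <- tab
    boxplots[[r]] <- lapply(stats::setNames(ss, vapply(
      ss, `[[`, "", "condition_label")), function(s)
        grDevices::boxplot.stats(s$samples[[r]])$stats)
    if (length(ss) >= 2) {
      prs <- utils::combn(length(ss), 2)
      comparisons[[r]] <- do.call(rbind, lapply(seq_len(ncol(prs)),
        function(k) {
          i <- prs[1, k]; j <- prs[2, k]
          ct <- compare_conditions(ss[[i]]$samples[[r]],
                                   ss[[j]]$samples[[r]])
          data.frame(readout = r,
                     condition_a = ss[[i]]$condition_label,
                     condition_b = ss[[j]]$condition_label,
                     u_statistic = ct$u_statistic, p_value = ct$p_value,
                     stars = significance_stars(ct$p_value))
        }))
    }
  }
  structure(list(tables = tables,
                 comparisons = if (length(comparisons))
                   do.call(rbind, comparisons) else NULL,
                 boxplots = boxplots,
                 footer = paste("Pairwise two-sided Mann-Whitney U tests;",
                                "no multiple-testing correction applied.")),
            class = "readout_report")
}

#' @export
print.readout_report <- function(x, ...) {
  for (r in names(x$tables)) {
    cat("==", r, "==\n")
    print(x$tables[[r]], row.names = FALSE)
  }
  if (!is.null(x$comparisons)) {
    cat("\n-- comparisons --\n")
    print(x$comparisons, row.names = FALSE)
  }
  cat("\n", x$footer, "\n", sep = "")
  invisible(x)
}
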