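#' Measurement table
#'
#' The per-subject, per-area table of mean displacements (mm) that feeds the
#' reliability and correlation analyses: a tibble with a `subject` column and
#' one numeric column per area. Light validation helper.
#'
#' @param x data frame with a `subject` column and numeric area columns.
#' @return The validated tibble.
#' @export
as_measurement_table <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"subject" %in% names(x)) stop("measurement table needs a 'subject' column")
  areas <- setdiff(names(x), "subject")
  if (length(areas) == 0) stop("measurement table has no area columns")
  bad <- areas[!vapply(x[areas], is.numeric, TRUE)]
  if (length(bad)) stop("non-numeric area columns: ", paste(bad, collapse = ", "))
  if (anyNA(x[areas])) stop("missing cells in the measurement table")
  x
}

measurement_areas <- function(x) setdiff(names(x), "subject")

# two-way mean squares for n subjects x k sessions (k = 2 here)
anova_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  resid <- m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Intra-rater repeatability: ICC(A,1)
#'
#' Two-way, absolute-agreement, single-measurement intraclass correlation
#' (McGraw & Wong's ICC(A,1)) between two measurement sessions of the same
#' rater, with the F-based 95% confidence interval. Absolute agreement is the
#' conservative choice for a repeatability study: a constant offset between
#' sessions lowers the coefficient. The model tag is carried in the result.
#'
#' @param session1,session2 paired numeric vectors (same subjects, same
#'   order), length >= 3.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return Object of class `dq_icc`: `icc`, `model_tag`, `n`, `ci95`,
#'   mean squares.
#' @export
icc_repeatability <- function(session1, session2, conf_level = 0.95) {
  if (length(session1) != length(session2))
    stop("sessions must be paired")
  n <- length(session1)
  if (n < 3) stop("need at least 3 subjects")
  m <- cbind(session1, session2)
  if (stats::var(session1) == 0 && stats::var(session2) == 0)
    stop("zero variance across subjects in both sessions: ICC undefined")
  ms <- anova_ms(m)
  k <- ms$k
  est <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
  alpha <- 1 - conf_level
  if (ms$mse == 0 && ms$msc == 0) {
    ci <- c(1, 1)  # duplicated sessions: agreement is exact
  } else {
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    if (!is.finite(a) || !is.finite(b)) {
      ci <- c(1, 1)
    } else {
      v <- (a * ms$msc + b * ms$mse)^2 /
        ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
      fl <- stats::qf(1 - alpha / 2, n - 1, v)
      fu <- stats::qf(1 - alpha / 2, v, n - 1)
      lower <- n * (ms$msr - fl * ms$mse) /
        (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
      upper <- n * (fu * ms$msr - ms$mse) /
        (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
      ci <- c(lower, upper)
    }
  }
  structure(list(icc = est, model_tag = "ICC(A,1) two-way absolute agreement, single measurement",
                 n = n, ci95 = ci, ms = ms),
            class = "dq_icc")
}

#' @export
print.dq_icc <- function(x, ...) {
  cat(sprintf("ICC = %.4f  [%s]  n = %d, 95%% CI %.4f to %.4f\n",
              x$icc, x$model_tag, x$n, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Per-area session-difference report
#'
#' Min/Max/Mean/SD of the paired between-session differences
#' (session2 - session1) per area, with the t-based 95% confidence interval
#' of the mean difference, plus the area's ICC — the repeatability table
#' layout of the study.
#'
#' @param session1,session2 measurement tables ([as_measurement_table()])
#'   with the same subjects and areas.
#' @return Tibble with one row per area: `area`, `icc`, `min`, `max`,
#'   `mean`, `sd`, `ci_lo`, `ci_hi`.
#' @export
difference_report <- function(session1, session2) {
  s1 <- as_measurement_table(session1)
  s2 <- as_measurement_table(session2)
  areas <- measurement_areas(s1)
  if (!identical(areas, measurement_areas(s2)))
    stop("sessions have different area sets")
  if (nrow(s1) != nrow(s2)) stop("sessions are not paired")
  n <- nrow(s1)
  if (n < 2) stop("need at least 2 subjects")
  purrr::map_dfr(areas, function(a) {
    d <- s2[[a]] - s1[[a]]
    m <- mean(d); s <- stats::sd(d)
    half <- stats::qt(0.975, n - 1) * s / sqrt(n)
    icc <- tryCatch(icc_repeatability(s1[[a]], s2[[a]])$icc,
                    error = function(e) NA_real_)
    tibble::tibble(area = a, icc = icc, min = min(d), max = max(d),
                   mean = m, sd = s, ci_lo = m - half, ci_hi = m + half)
  })
}

#' Per-area descriptive statistics
#'
#' Min/Max/Mean/SD (sample SD, n-1) of each area's displacement across
#' subjects — the descriptive-table layout. A single subject yields
#' Min = Max = Mean and an empty SD.
#'
#' @param table a measurement table.
#' @return Tibble: `area`, `n`, `min`, `max`, `mean`, `sd`.
#' @export
descriptives <- function(table) {
  t <- as_measurement_table(table)
  purrr::map_dfr(measurement_areas(t), function(a) {
    x <- t[[a]]
    tibble::tibble(area = a, n = length(x), min = min(x), max = max(x),
                   mean = mean(x),
                   sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  })
}

# ---- Spearman with exact permutation p at small n ---------------------------

perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  P <- matrix(1L, 1, 1)
  if (n > 1) {
    for (m in 2:n) {
      k <- nrow(P)
      parts <- vector("list", m)
      for (pos in 1:m) {
        left <- P[, seq_len(pos - 1), drop = FALSE]
        right <- P[, if (pos <= m - 1) pos:(m - 1) else integer(0), drop = FALSE]
        parts[[pos]] <- cbind(left, matrix(m, k, 1), right)
      }
      P <- do.call(rbind, parts)
    }
  }
  storage.mode(P) <- "integer"
  perm_cache[[key]] <- P
  P
}

rho_of_ranks <- function(rx, ry) {
  # Pearson correlation of (average) ranks = Spearman with tie correction
  suppressWarnings(stats::cor(rx, ry))
}

# sorted |rho| over all permutations of untied ranks 1..n; the permutation
# null is the same for every tie-free sample of size n, so cache it
null_abs_rho <- function(n) {
  key <- paste0("null", n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  P <- all_permutations(n)
  r <- seq_len(n)
  a <- (r - mean(r)) / stats::sd(r)
  ryp <- matrix(r[P], nrow(P), n)
  rho <- (ryp %*% a) / ((n - 1) * stats::sd(r))
  out <- sort(abs(as.numeric(rho)))
  perm_cache[[key]] <- out
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Spearman's rho with average ranks for ties. The two-sided p-value is
#' computed by exact enumeration of all n! rank permutations when n <= 9
#' (at n = 8 that is 40,320 permutations — cheap, and the asymptotic
#' approximation is poor there), and by the t approximation otherwise. The
#' method used is recorded in the result.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return Object of class `dq_spearman`: `rho`, `p_value`, `n`, `method`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("zero rank variance: correlation undefined")
  rho <- rho_of_ranks(rx, ry)
  ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  if (n <= 9 && !ties) {
    null <- null_abs_rho(n)
    nn <- length(null)
    p <- (nn - findInterval(abs(rho) - 1e-12, null)) / nn
    method <- "exact permutation"
  } else if (n <= 9) {
    P <- all_permutations(n)
    ryp <- matrix(ry[P], nrow(P), n)
    a <- (rx - mean(rx)) / stats::sd(rx)
    sy <- stats::sd(ry)
    # sum(a) = 0, so centring ry is unnecessary in the inner product
    rho_perm <- (ryp %*% a) / ((n - 1) * sy)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    p <- min(max(p, .Machine$double.xmin), 1)
    method <- "t approximation"
  }
  structure(list(rho = rho, p_value = p, n = n, method = method),
            class = "dq_spearman")
}

#' @export
print.dq_spearman <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, two-sided p = %.4g (n = %d, %s)\n",
              x$rho, x$p_value, x$n, x$method))
  invisible(x)
}

#' Hard-soft correlation matrix
#'
#' Spearman correlations between all pairs of areas in one area set, with
#' exact permutation p-values at small n, rendered the way the study tables
#' are laid out: correlations below the diagonal, p-values above, and
#' significant cells (p < alpha) marked. No multiple-testing correction by
#' default, matching the "significance at p < 0.05 per pair" convention; a
#' Holm adjustment is available behind `adjust`.
#'
#' @param table a measurement table.
#' @param areas `"maxillary"`, `"mandibular"`, or a character vector of area
#'   names, all of which must be present.
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Object of class `dq_cormat`: `r`, `p`, `significant` matrices,
#'   `alpha`, `areas`, `n`.
#' @export
correlation_matrix <- function(table, areas = "maxillary", alpha = 0.05,
                               adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  t <- as_measurement_table(table)
  if (length(areas) == 1 && areas %in% c("maxillary", "mandibular"))
    areas <- area_set(areas)
  missing <- setdiff(areas, names(t))
  if (length(missing))
    stop("missing area(s): ", paste(missing, collapse = ", "))
  if (nrow(t) < 3) stop("need at least 3 subjects for correlations")
  k <- length(areas)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(areas, areas))
  for (i in seq_len(k)) {
    for (j in seq_len(i - 1L)) {
      s <- spearman(t[[areas[i]]], t[[areas[j]]])
      r[i, j] <- r[j, i] <- s$rho
      p[i, j] <- p[j, i] <- s$p_value
    }
  }
  if (adjust == "holm") {
    lower <- lower.tri(p)
    p[lower] <- stats::p.adjust(p[lower], "holm")
    p[upper.tri(p)] <- t(p)[upper.tri(p)]
  }
  sig <- !is.na(p) & p < alpha
  structure(list(r = r, p = p, significant = sig, alpha = alpha,
                 areas = areas, n = nrow(t)),
            class = "dq_cormat")
}

#' @export
format.dq_cormat <- function(x, digits = 2, ...) {
  k <- length(x$areas)
  out <- matrix("-", k, k, dimnames = list(x$areas, x$areas))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      if (i > j) {  # lower triangle: r
        out[i, j] <- sprintf(paste0("%.", digits, "f"), x$r[i, j])
      } else {      # upper triangle: p
        pv <- x$p[i, j]
        out[i, j] <- if (pv < 0.01) "<0.01"
                     else sprintf(paste0("%.", digits, "f"), pv)
      }
      if (x$significant[i, j]) out[i, j] <- paste0(out[i, j], "*")
    }
  }
  out
}

#' @export
print.dq_cormat <- function(x, ...) {
  cat(sprintf(
    "Spearman correlation matrix (n = %d): r below / p above the dashes; '*' p < %.2g\n",
    x$n, x$alpha))
  print(format(x), quote = FALSE)
  invisible(x)
}
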