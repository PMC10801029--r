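#' Ratings table for a multi-rater ordinal survey
#'
#' Long-format ratings on the 3-level agreement scale
#' (False = 1, Partially True = 2, True = 3), with missing responses allowed.
#'
#' @param data data frame with columns `item`, `subject`, `rater`,
#'   `response`. Responses may be integers `1..K` or the labels
#'   `"False"`, `"Partially True"`, `"True"`; blank / NA = missing.
#' @param K number of ordinal categories (default 3).
#' @return An object of class `ratings_table`: the cleaned long data frame
#'   (missing rows dropped) plus `K`.
#' @export
ratings_table <- function(data, K = 3L) {
  stopifnot(all(c("item", "subject", "rater", "response") %in% names(data)))
  resp <- data$response
  if (!is.numeric(resp)) {
    lab <- c("False" = 1L, "Partially True" = 2L, "True" = 3L)
    chr <- trimws(as.character(resp))
    num <- suppressWarnings(as.numeric(chr))
    resp <- ifelse(!is.na(num), num, unname(lab[chr]))
    resp[chr == ""] <- NA
  }
  resp <- as.integer(resp)
  keep <- !is.na(resp)
  if (any(resp[keep] < 1L | resp[keep] > K)) {
    stop("responses must be in 1..", K, " (or the matching labels)")
  }
  out <- data.frame(item = as.character(data$item[keep]),
                    subject = as.character(data$subject[keep]),
                    rater = as.character(data$rater[keep]),
                    response = resp[keep],
                    stringsAsFactors = FALSE)
  structure(list(data = out, K = as.integer(K)), class = "ratings_table")
}

#' Read a ratings CSV
#'
#' Columns `item, subject, rater, response`; responses as `1|2|3` or
#' `False|Partially True|True`; blank cells are missing.
#'
#' @param path CSV file.
#' @param K categories (default 3).
#' @return A [ratings_table()].
#' @export
read_ratings <- function(path, K = 3L) {
  ratings_table(utils::read.csv(path, stringsAsFactors = FALSE), K = K)
}

#' Ordinal agreement weights
#'
#' Gwet's ordinal weights for K ordered categories:
#' `w_kl = 1 - C(|k - l| + 1, 2) / C(K, 2)` with `C` the binomial
#' coefficient. Symmetric with unit diagonal; adjacent categories receive
#' partial credit.
#'
#' @param K number of categories (>= 2).
#' @return K x K numeric weight matrix.
#' @export
ordinal_weights <- function(K) {
  if (K < 2) stop("need at least 2 categories")
  d <- abs(outer(seq_len(K), seq_len(K), `-`))
  1 - choose(d + 1, 2) / choose(K, 2)
}

# subject x category count matrix r_ik from one item's long ratings
rating_counts <- function(df, K) {
  subj <- unique(df$subject)
  r <- matrix(0L, length(subj), K, dimnames = list(subj, NULL))
  for (k in seq_len(K)) {
    tab <- table(df$subject[df$response == k])
    r[names(tab), k] <- as.integer(tab)
  }
  r
}

ac2_from_counts <- function(r, W, K) {
  ri <- rowSums(r)
  if (!any(ri >= 2)) stop("pa undefined: all subjects have fewer than 2 ratings")
  rstar <- r %*% W
  multi <- ri >= 2
  pa_i <- rowSums(r[multi, , drop = FALSE] *
                    (rstar[multi, , drop = FALSE] - 1)) /
    (ri[multi] * (ri[multi] - 1))
  pa <- mean(pa_i)
  pik <- colMeans(r[ri >= 1, , drop = FALSE] / ri[ri >= 1])
  Tw <- sum(W)
  pe <- (Tw / (K * (K - 1))) * sum(pik * (1 - pik))
  if (1 - pe < 1e-12) stop("degenerate coefficient: chance agreement is 1")
  list(pa = pa, pe = pe, ac2 = (pa - pe) / (1 - pe), n_subjects = nrow(r),
       n_ratings = sum(ri))
}

#' Gwet's AC2 agreement coefficient with ordinal weighting
#'
#' Chance-corrected inter-rater agreement for ordinal ratings, robust to
#' missing responses and to high observed agreement. With `r_ik` the number
#' of raters placing subject i in category k, `r_i` the raters of subject i
#' and `r*_ik = sum_l w_kl r_il`: percent agreement
#' `pa = mean over subjects with r_i >= 2 of sum_k r_ik (r*_ik - 1) /
#' (r_i (r_i - 1))`; chance agreement
#' `pe = (T_w / (K (K-1))) sum_k pi_k (1 - pi_k)` with `pi_k` the average
#' classification probability over all rated subjects and `T_w` the sum of
#' the weights; `AC2 = (pa - pe) / (1 - pe)`. Single-rated subjects
#' contribute to `pe` but not `pa`. The standard error comes from a
#' delete-one-subject jackknife and the two-sided p-value from a t reference
#' with n - 1 degrees of freedom for the null of zero agreement.
#'
#' @param ratings a [ratings_table()], a long data frame with the same
#'   columns (single item), or a subjects x raters matrix of responses with
#'   NA for missing.
#' @param K number of categories (taken from a `ratings_table`).
#' @param weights K x K weight matrix (default [ordinal_weights()]).
#' @return An `agreement_result`: list with `pa`, `pe`, `ac2`, `se`, `p`,
#'   `n_subjects`, `n_ratings` and benchmark `label`.
#' @export
gwet_ac2 <- function(ratings, K = NULL, weights = NULL) {
  if (inherits(ratings, "ratings_table")) {
    K <- ratings$K
    df <- ratings$data
    if (length(unique(df$item)) > 1L) {
      stop("gwet_ac2 expects a single item; see survey_report() for many")
    }
  } else if (is.matrix(ratings)) {
    K <- if (is.null(K)) max(ratings, na.rm = TRUE) else K
    df <- data.frame(
      subject = rep(rownames(ratings) %||% as.character(seq_len(nrow(ratings))),
                    ncol(ratings)),
      response = as.vector(ratings))
    df <- df[!is.na(df$response), ]
  } else {
    df <- as.data.frame(ratings)
    if (is.null(K)) K <- max(df$response)
  }
  W <- if (is.null(weights)) ordinal_weights(K) else weights
  r <- rating_counts(df, K)
  res <- ac2_from_counts(r, W, K)

  n <- nrow(r)
  jack <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ji <- tryCatch(ac2_from_counts(r[-i, , drop = FALSE], W, K)$ac2,
                   error = function(e) NA_real_)
    jack[i] <- ji
  }
  jack <- jack[!is.na(jack)]
  m <- length(jack)
  se <- if (m >= 2) sqrt((m - 1) / m * sum((jack - mean(jack))^2)) else NA_real_
  p <- if (!is.na(se) && se > 0) {
    2 * stats::pt(-abs(res$ac2 / se), df = n - 1)
  } else NA_real_
  structure(c(res, list(se = se, p = p, label = benchmark_label(res$ac2))),
            class = "agreement_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Gwet AC2 = %.4f (pa = %.4f, pe = %.4f, SE = %s, p = %s) [%s]\n",
              x$ac2, x$pa, x$pe,
              ifelse(is.na(x$se), "NA", sprintf("%.4f", x$se)),
              ifelse(is.na(x$p), "NA", format.pval(x$p, digits = 3)),
              x$label))
  invisible(x)
}

#' Agreement coefficient from printed percent/chance agreement
#'
#' The defining identity `AC2 = (pa - pe) / (1 - pe)`, exposed so that
#' published percent-agreement and chance-agreement pairs can be converted to
#' the coefficient.
#'
#' @param pa percent agreement in \[0, 1\].
#' @param pe chance agreement in \[0, 1).
#' @return The coefficient.
#' @export
ac2_from_agreement <- function(pa, pe) {
  stopifnot(all(pa >= 0 & pa <= 1), all(pe >= 0 & pe < 1))
  (pa - pe) / (1 - pe)
}

#' Benchmark label for an agreement coefficient
#'
#' Classifies a coefficient on the reliability benchmark scale:
#' <= 0.20 poor, 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 substantial,
#' 0.81-1.0 excellent. The coefficient is rounded to 2 decimal places first
#' so the closed printed ranges cover gap values; negative coefficients are
#' poor.
#'
#' @param coef agreement coefficient(s), <= 1.
#' @return Character label(s).
#' @export
benchmark_label <- function(coef) {
  stopifnot(all(coef <= 1 + 1e-9))
  x <- round(coef, 2)
  cut(x, breaks = c(-Inf, 0.20, 0.40, 0.60, 0.80, 1),
      labels = c("poor", "fair", "moderate", "substantial", "excellent"),
      right = TRUE) |> as.character()
}

#' Stuart-Maxwell test of marginal homogeneity
#'
#' Generalized McNemar chi-squared test for a K x K paired contingency
#' table: with `d_k = row_k - col_k` and covariance
#' `S_kk = row_k + col_k - 2 t_kk`, `S_kl = -(t_kl + t_lk)`, one category is
#' dropped and `chi2 = d' S^-1 d` on K - 1 degrees of freedom. Categories
#' with no off-diagonal involvement are collapsed out first (reducing the
#' degrees of freedom); a symmetric table gives chi2 = 0, p = 1.
#'
#' @param t K x K matrix of paired counts (rows = first condition,
#'   columns = second).
#' @return List with `chi2`, `dof`, `p`.
#' @export
stuart_maxwell <- function(t) {
  t <- as.matrix(t)
  if (nrow(t) != ncol(t) || nrow(t) < 2) stop("need a square K x K table, K >= 2")
  if (any(t < 0) || any(t != round(t))) stop("counts must be non-negative integers")
  K <- nrow(t)
  rs <- rowSums(t); cs <- colSums(t)
  # drop categories never involved in a disagreement
  keep <- (rs + cs - 2 * diag(t)) > 0
  if (sum(keep) < 2) {
    if (all(t == t(t))) return(list(chi2 = 0, dof = max(1L, K - 1L), p = 1))
    stop("test undefined: no estimable contrast after collapsing")
  }
  tk <- t[keep, keep, drop = FALSE]
  Kk <- nrow(tk)
  rs <- rowSums(tk); cs <- colSums(tk)
  d <- (rs - cs)[-Kk]
  S <- -(tk + t(tk))
  diag(S) <- rs + cs - 2 * diag(tk)
  S <- S[-Kk, -Kk, drop = FALSE]
  chi2 <- tryCatch(as.numeric(crossprod(d, solve(S, d))),
                   error = function(e) stop("test undefined: singular covariance"))
  dof <- Kk - 1L
  list(chi2 = chi2, dof = dof, p = stats::pchisq(chi2, dof, lower.tail = FALSE))
}

#' Spearman rank correlation with small-sample exact p
#'
#' Correlation of mid-ranks (ties averaged). The two-sided p-value is exact
#' by full enumeration of the n! rank permutations when n <= 8 and there are
#' no ties; otherwise it uses the t approximation with n - 2 degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `rho`, `p`, and `method` ("exact" or "t").
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("rho undefined: constant input vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 8 && !ties) {
    perms <- permutations_of(n)
    # no ties: rho = 1 - 6 sum d^2 / (n (n^2 - 1)) for each permuted ranking
    d2 <- colSums((t(perms) - rx)^2)
    rho_all <- 1 - 6 * d2 / (n * (n^2 - 1))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t"
  }
  list(rho = rho, p = min(p, 1), method = method)
}

# all permutations of 1..n as an n! x n matrix (n <= 8)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    blk <- cbind(if (pos > 1) sub[, seq_len(pos - 1), drop = FALSE],
                 n,
                 if (pos <= n - 1) sub[, pos:(n - 1), drop = FALSE])
    out[row:(row + nrow(sub) - 1L), ] <- blk
    row <- row + nrow(sub)
  }
  out
}

#' Multiple-comparison adjustment
#'
#' Bonferroni by default (p times m, capped at 1); Holm's step-down method
#' by flag. Order of the input is preserved.
#'
#' @param ps p-values in \[0, 1\].
#' @param method "bonferroni" (default) or "holm".
#' @return Adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(ps, method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  stopifnot(all(ps >= 0 & ps <= 1))
  stats::p.adjust(ps, method = method)
}

#' Simulate a multi-rater ordinal survey
#'
#' Independent draws per rater from per-subject category probabilities, with
#' responses removed completely at random at the given rate. A subject that
#' loses every rating is redrawn once; if it is again empty it is dropped
#' with a warning. Deterministic given the seed.
#'
#' @param n_subjects,n_raters survey dimensions.
#' @param probs length-K probability vector, or an n_subjects x K matrix of
#'   per-subject probabilities.
#' @param missing_rate probability a response is missing, in \[0, 1).
#' @param seed RNG seed.
#' @param item item label for the output table.
#' @return A [ratings_table()].
#' @export
simulate_ratings <- function(n_subjects, n_raters, probs,
                             missing_rate = 0, seed = 1L, item = "item1") {
  if (missing_rate < 0 || missing_rate >= 1) stop("missing rate must be in [0, 1)")
  if (is.vector(probs)) probs <- matrix(probs, n_subjects, length(probs), byrow = TRUE)
  if (nrow(probs) != n_subjects) stop("probs must have one row per subject")
  if (any(abs(rowSums(probs) - 1) > 1e-8)) stop("probabilities must sum to 1 per subject")
  K <- ncol(probs)
  with_seed(seed, {
    draw_subject <- function(i) {
      resp <- sample.int(K, n_raters, replace = TRUE, prob = probs[i, ])
      resp[stats::runif(n_raters) < missing_rate] <- NA
      resp
    }
    rows <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      resp <- draw_subject(i)
      if (all(is.na(resp))) resp <- draw_subject(i)   # resample once
      if (all(is.na(resp))) {
        warning("subject ", i, " lost all ratings; dropped")
        next
      }
      rows[[i]] <- data.frame(item = item,
                              subject = sprintf("s%03d", i),
                              rater = sprintf("r%02d", seq_len(n_raters)),
                              response = resp)
    }
    df <- do.call(rbind, rows)
    ratings_table(df, K = K)
  })
}

#' Per-item survey agreement report
#'
#' Runs [gwet_ac2()] on every item of a ratings table and adjusts the
#' p-values across items.
#'
#' @param ratings a [ratings_table()] (possibly many items).
#' @param adjust multiplicity method for [adjust_pvalues()].
#' @return Data frame with one row per item: `item`, `n_ratings`, `pa`,
#'   `pe`, `ac2`, `se`, `p`, `p_adj`, `label`.
#' @export
survey_report <- function(ratings, adjust = "bonferroni") {
  stopifnot(inherits(ratings, "ratings_table"))
  items <- unique(ratings$data$item)
  rows <- lapply(items, function(it) {
    sub <- ratings_table(ratings$data[ratings$data$item == it, ], K = ratings$K)
    r <- gwet_ac2(sub)
    data.frame(item = it, n_ratings = r$n_ratings, pa = r$pa, pe = r$pe,
               ac2 = r$ac2, se = r$se, p = r$p, label = r$label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_pvalues(out$p, method = adjust)
  out[, c("item", "n_ratings", "pa", "pe", "ac2", "se", "p", "p_adj", "label")]
}
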