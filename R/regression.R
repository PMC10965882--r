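## Luminance-controlled stepwise model selection, collinearity diagnostics,
## and the repeated-measures power utility.

#' Regress luminance out of a response
#'
#' Returns the residuals of an ordinary least-squares fit of `y` on an
#' intercept and mean image luminance, removing the luminance contribution
#' from the eye-movement data before model selection.  Residuals have mean
#' zero and are exactly uncorrelated with `lum`.
#'
#' @param y response vector.
#' @param lum luminance vector (same length, at least 3 points).
#' @return Residual vector.
#' @export
residualize_luminance <- function(y, lum) {
  stopifnot(length(y) == length(lum), length(y) >= 3)
  if (sd(lum) == 0) {
    warning("constant luminance: returning centered response")
    return(y - mean(y))
  }
  unname(resid(lm(y ~ lum)))
}

#' Bidirectional stepwise AIC model selection
#'
#' Greedy search over single add/drop moves minimizing AIC (penalty k = 2),
#' starting from the full model.  At every step the move (or staying put)
#' with the lowest AIC is taken; exact ties are broken toward the smaller
#' model and then alphabetically by predictor name, so the result is
#' deterministic and invariant to column permutation of `X`.  Columns that
#' are exactly collinear with earlier columns are dropped up front with a
#' warning.
#'
#' @param y response vector (typically luminance residuals).
#' @param X data.frame or matrix of candidate predictors (no missing
#'   values).
#' @param direction `"both"`, `"backward"` (drops only) or `"forward"`
#'   (starts empty, adds only).
#' @param warn_small warn when `n < 3 * p` (small-sample selection is
#'   unstable; category-level fits fall in this regime).
#' @return Object of class `stepwise_fit`: list with `selected` (predictor
#'   names), `coefficients` (data.frame: term, estimate, std_error, t, p),
#'   `adj_r_squared`, `aic_trace`, `model` (the final `lm` fit).
#' @export
stepwise_aic <- function(y, X, direction = c("both", "backward", "forward"),
                         warn_small = TRUE) {
  direction <- match.arg(direction)
  X <- as.data.frame(X)
  stopifnot(!anyNA(y), !anyNA(X), nrow(X) == length(y))
  if (warn_small && nrow(X) < 3 * ncol(X))
    warning(sprintf("only %d observations for %d candidates: selection is unstable",
                    nrow(X), ncol(X)))
  # drop exactly collinear columns (keep the earliest of each aliased group)
  qx <- qr(cbind(`(Intercept)` = 1, as.matrix(X)))
  if (qx$rank < ncol(X) + 1) {
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    keep <- setdiff(keep, 1) - 1
    dropped <- setdiff(names(X), names(X)[keep])
    warning("dropping exactly collinear column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  dat <- cbind(.y = y, X)
  fit_set <- function(set) {
    fml <- if (length(set)) stats::reformulate(sprintf("`%s`", set),
                                               response = ".y")
    else .y ~ 1
    lm(fml, data = dat)
  }
  current <- if (direction == "forward") character(0) else names(X)
  cur_fit <- fit_set(current)
  cur_aic <- AIC(cur_fit)
  trace <- data.frame(step = 0L, move = "start", aic = cur_aic,
                      size = length(current), stringsAsFactors = FALSE)
  repeat {
    moves <- list()
    if (direction != "forward")
      for (p in current) moves[[paste0("- ", p)]] <- setdiff(current, p)
    if (direction != "backward")
      for (p in setdiff(names(X), current))
        moves[[paste0("+ ", p)]] <- c(current, p)
    if (!length(moves)) break
    aics <- vapply(moves, function(s) AIC(fit_set(s)), numeric(1))
    sizes <- vapply(moves, length, integer(1))
    # candidate order: AIC, then model size, then alphabetical move label
    lab <- names(moves)
    ord <- order(aics, sizes, substring(lab, 3))
    best <- ord[1]
    better <- aics[best] < cur_aic - 1e-10 ||
      (aics[best] <= cur_aic + 1e-10 && sizes[best] < length(current))
    if (!better) break
    current <- moves[[best]]
    cur_fit <- fit_set(current)
    cur_aic <- aics[best]
    trace <- rbind(trace, data.frame(step = nrow(trace), move = lab[best],
                                     aic = cur_aic, size = length(current),
                                     stringsAsFactors = FALSE))
  }
  sm <- summary(cur_fit)
  ct <- coef(sm)
  coefs <- data.frame(term = rownames(ct), estimate = ct[, 1],
                      std_error = ct[, 2], t = ct[, 3], p = ct[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  coefs$term <- gsub("`", "", coefs$term)
  structure(list(selected = sort(current), coefficients = coefs,
                 adj_r_squared = sm$adj.r.squared, aic_trace = trace,
                 model = cur_fit),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("Stepwise AIC fit: ", length(x$selected), " predictor(s) [",
      paste(x$selected, collapse = ", "), "], adj R^2 = ",
      sprintf("%.3f", x$adj_r_squared), "\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Image-level and category-level regression suite
#'
#' For each eye-movement response, regresses out luminance and performs
#' bidirectional stepwise AIC selection over the image-statistic candidate
#' columns, mirroring the standard two-level analysis (240 images, or 12
#' category means with a small-sample warning).
#'
#' @param data data.frame holding responses, predictors and `luminance`.
#' @param responses character vector of response column names.
#' @param predictors character vector of candidate predictor columns.
#' @param level label stored in the results (`"image"` or `"category"`).
#' @return Named list of `stepwise_fit` objects, one per response, each
#'   carrying `response` and `level` attributes.
#' @export
regress_gaze_on_stats <- function(data, responses, predictors,
                                  level = "image") {
  stopifnot(all(c(responses, predictors, "luminance") %in% names(data)))
  cc <- complete.cases(data[c(responses, predictors, "luminance")])
  if (!all(cc)) data <- data[cc, , drop = FALSE]
  out <- lapply(responses, function(r) {
    ry <- residualize_luminance(data[[r]], data$luminance)
    fit <- stepwise_aic(ry, data[predictors],
                        warn_small = identical(level, "category"))
    attr(fit, "response") <- r
    attr(fit, "level") <- level
    fit
  })
  names(out) <- responses
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor
#' `j` on all the others.  Perfectly collinear predictors report `Inf`.
#'
#' @param X data.frame or matrix of at least two predictors.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.data.frame(X)
  stopifnot(ncol(X) >= 2)
  vapply(names(X), function(j) {
    fml <- stats::as.formula(paste0(
      "`", j, "` ~ ", paste0("`", setdiff(names(X), j), "`", collapse = " + ")))
    r2 <- summary(lm(fml, data = X))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Power of the repeated-measures within-factor F test
#'
#' Noncentral-F power with `df1 = m - 1`, `df2 = (n - 1) (m - 1)` and
#' noncentrality `lambda = f^2 m n / (1 - rho)`, where `f` is Cohen's f,
#' `m` the number of measurement levels, `n` the number of subjects and
#' `rho` the correlation among repeated measures.  No sphericity
#' correction is applied (the convention of the standard power tools).
#'
#' @param f Cohen's f effect size (> 0).
#' @param m measurement levels (>= 2).
#' @param n subjects (>= 2).
#' @param alpha significance level.
#' @param rho repeated-measures correlation in `[0, 1)`.
#' @return Statistical power in `(0, 1)`.
#' @export
rm_anova_power <- function(f, m, n, alpha = 0.05, rho = 0.5) {
  stopifnot(f > 0, m >= 2, n >= 2, alpha > 0, alpha < 1, rho >= 0, rho < 1)
  lambda <- f^2 * m * n / (1 - rho)
  df1 <- m - 1
  df2 <- (n - 1) * (m - 1)
  pf(qf(1 - alpha, df1, df2), df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Minimal sample size for a target power
#'
#' Smallest `n` whose [rm_anova_power()] reaches `target_power`.
#' @inheritParams rm_anova_power
#' @param target_power required power.
#' @param n_max search limit.
#' @return Integer sample size.
#' @export
required_n <- function(f, m, alpha = 0.05, target_power = 0.8, rho = 0.5,
                       n_max = 100000L) {
  for (n in 2:n_max)
    if (rm_anova_power(f, m, n, alpha, rho) >= target_power) return(n)
  stop("target power not reachable with n <= ", n_max)
}
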