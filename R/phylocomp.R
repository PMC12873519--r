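#' Read and validate a phylogenetic tree from Newick
#'
#' Thin wrapper around [ape::read.tree()] that insists on branch lengths and
#' unique tip labels, and attaches a small concordance/shape report
#' (`attr(tree, "tree_report")`): tip count, whether the tree is binary, and
#' whether it is ultrametric (relative tolerance 1e-6).
#'
#' @param source Path to a Newick file, or a Newick string (must contain
#'   `"("`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(source) {
  tr <- tryCatch({
    if (length(source) == 1L && grepl("(", source, fixed = TRUE))
      ape::read.tree(text = source)
    else
      ape::read.tree(file = source)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("could not parse Newick input: ", substr(paste(source, collapse = " "), 1, 60),
         call. = FALSE)
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths; time-calibrated branch lengths are required",
         call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (any(tr$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  attr(tr, "tree_report") <- list(
    n_tips = length(tr$tip.label),
    binary = ape::is.binary(tr),
    ultrametric = ape::is.ultrametric(tr, option = 2, tol = 1e-6)
  )
  tr
}

#' Tree depth (maximum root-to-tip path length)
#' @param tree A `phylo` object.
#' @return Numeric depth.
#' @keywords internal
tree_depth <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

#' Randomly resolve polytomies while preserving tip depths
#'
#' Multifurcations are replaced by randomly ordered bifurcations
#' ([ape::multi2di()] with `random = TRUE`, seeded). Each new internal edge
#' is given a small positive length (1e-8 times the tree depth) so that
#' phylogenetic covariance matrices stay non-singular, and every tip's
#' terminal edge is shortened by its path's accumulated surplus so root-to-tip
#' depths are unchanged.
#'
#' @param tree An ultrametric `phylo` object.
#' @param seed Integer seed controlling the random bifurcation orders.
#' @return A binary ultrametric `phylo` object.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.ultrametric(tree, option = 2, tol = 1e-6))
    stop("input tree is not ultrametric (relative tolerance 1e-6)", call. = FALSE)
  if (ape::is.binary(tree)) return(tree)
  depth0 <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  set.seed(as.integer(seed))
  tr <- ape::multi2di(tree, random = TRUE)
  eps <- 1e-8 * tree_depth(tree)
  ntip <- length(tr$tip.label)
  zero_int <- which(tr$edge.length == 0 & tr$edge[, 2] > ntip)
  tr$edge.length[zero_int] <- eps
  # restore each tip's original depth by trimming its terminal edge
  depth1 <- ape::node.depth.edgelength(tr)[seq_len(ntip)]
  names(depth0) <- tree$tip.label
  surplus <- depth1 - depth0[tr$tip.label]
  term <- match(seq_len(ntip), tr$edge[, 2])
  if (any(tr$edge.length[term] < surplus))
    stop("terminal edges too short to absorb polytomy epsilon branches", call. = FALSE)
  tr$edge.length[term] <- tr$edge.length[term] - surplus
  tr
}

#' Residual correlation structure for phylogenetic GLS
#'
#' @param kind One of `"WN"` (white noise, phylogenetic independence),
#'   `"BM"` (Brownian motion), `"OU"` (Ornstein-Uhlenbeck, correlation
#'   `exp(-alpha * d)` with `d` the patristic distance), or `"lambda"`
#'   (Pagel's lambda transform of the BM covariance).
#' @param alpha OU mean-reversion rate, in units of 1/tree depth (default 1).
#' @param lambda Pagel's lambda in `[0, 1]` (default 1; `lambda = 0`
#'   reproduces white noise).
#' @return An object of class `correlation_structure`.
#' @export
correlation_structure <- function(kind = c("WN", "BM", "OU", "lambda"),
                                  alpha = 1, lambda = 1) {
  kind <- match.arg(kind)
  if (kind == "OU" && (!is.finite(alpha) || alpha <= 0))
    stop("OU 'alpha' must be positive", call. = FALSE)
  if (kind == "lambda" && (!is.finite(lambda) || lambda < 0 || lambda > 1))
    stop("'lambda' must lie in [0, 1]", call. = FALSE)
  structure(list(kind = kind, alpha = alpha, lambda = lambda),
            class = "correlation_structure")
}

#' Species-by-species trait covariance implied by a tree
#'
#' White noise gives the identity; Brownian motion gives shared-ancestor
#' depths (diagonal = total depth); OU gives correlation
#' `exp(-alpha * d_ij)` with `d_ij` the patristic distance; the lambda
#' transform multiplies BM off-diagonals by `lambda`.
#'
#' @param tree An ultrametric `phylo` object.
#' @param structure A [correlation_structure()], or a kind string.
#' @param tips Optional character vector: restrict and order rows/columns to
#'   these tips (must all be in the tree).
#' @return A symmetric positive semi-definite matrix with tip-label dimnames.
#' @export
covariance_matrix <- function(tree, structure = "BM", tips = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.character(structure)) structure <- correlation_structure(structure)
  stopifnot(inherits(structure, "correlation_structure"))
  if (!is.null(tips)) {
    missing <- setdiff(tips, tree$tip.label)
    if (length(missing))
      stop("tips not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  lab <- if (is.null(tips)) tree$tip.label else tips
  C <- switch(structure$kind,
    WN = diag(length(lab)),
    BM = ape::vcv.phylo(tree)[lab, lab, drop = FALSE],
    OU = exp(-structure$alpha * ape::cophenetic.phylo(tree)[lab, lab, drop = FALSE]),
    lambda = {
      V <- ape::vcv.phylo(tree)[lab, lab, drop = FALSE]
      D <- diag(V)
      V <- structure$lambda * V
      diag(V) <- D
      V
    })
  dimnames(C) <- list(lab, lab)
  (C + t(C)) / 2
}

# Cholesky with a logged jitter fallback; errors if still singular.
.safe_chol <- function(C) {
  U <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(U)) {
    jit <- 1e-10 * sum(diag(C)) / nrow(C)
    message("covariance matrix near-singular; adding jitter ", signif(jit, 3),
            " to the diagonal")
    U <- tryCatch(chol(C + diag(jit, nrow(C))), error = function(e) NULL)
    if (is.null(U))
      stop("covariance matrix singular even after diagonal jitter", call. = FALSE)
  }
  U
}

#' Generalized least squares under a fixed residual covariance
#'
#' Fits `y = X beta + eps`, `eps ~ N(0, sigma^2 C)` with `C` fixed, by
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`, with `sigma^2` profiled by maximum
#' likelihood (`sigma^2 = r' C^-1 r / n`). With `C = I` the coefficients are
#' identical to ordinary least squares. Reports the Gaussian log-likelihood,
#' AIC and AICc, counting the regression coefficients plus the residual
#' variance as free parameters.
#'
#' @param y Numeric response vector.
#' @param X Design matrix (include the intercept column yourself, or pass a
#'   one-column predictor and `intercept = TRUE`).
#' @param covariance Square covariance matrix `C` (same order as `y`).
#' @param intercept If `TRUE` and `X` lacks an all-ones column, prepend one.
#' @param structure_name Optional label stored in the result (e.g. `"WN"`).
#' @return An object of class `gls_fit` with coefficients, standard errors,
#'   95\% confidence intervals, `logLik`, `AIC`, `AICc`, `sigma2`, `n`, `df`.
#' @export
gls_fit <- function(y, X, covariance, intercept = TRUE,
                    structure_name = "custom") {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (intercept && !any(apply(X, 2, function(col) all(col == 1))))
    X <- cbind(`(Intercept)` = 1, X)
  n <- length(y)
  if (nrow(X) != n || nrow(covariance) != n || ncol(covariance) != n)
    stop("dimension mismatch between y, X and covariance", call. = FALSE)
  p <- ncol(X)
  if (n <= p) stop("need more observations than coefficients", call. = FALSE)
  U <- .safe_chol(covariance)            # C = U'U
  yt <- backsolve(U, y, transpose = TRUE)  # U'^-1 y
  Xt <- backsolve(U, X, transpose = TRUE)
  qr_ <- qr(Xt)
  beta <- qr.coef(qr_, yt)
  r <- yt - Xt %*% beta
  rss <- sum(r^2)
  sigma2 <- rss / n
  XtX_inv <- chol2inv(qr.R(qr_))
  se <- sqrt(diag(XtX_inv) * rss / (n - p))
  df <- n - p
  tq <- stats::qt(0.975, df)
  logdetC <- 2 * sum(log(diag(U)))
  ll <- -n / 2 * log(2 * pi * sigma2) - logdetC / 2 - n / 2
  k <- p + 1
  aic <- -2 * ll + 2 * k
  aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  ci <- cbind(lower = as.numeric(beta) - tq * se,
              upper = as.numeric(beta) + tq * se)
  rownames(ci) <- nm
  structure(list(
    coefficients = stats::setNames(as.numeric(beta), nm),
    se = stats::setNames(se, nm),
    ci = ci,
    sigma2 = sigma2, logLik = ll, AIC = aic, AICc = aicc,
    structure = structure_name, n = n, df = df, p = p
  ), class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("Generalized least squares fit [", x$structure, "], n = ", x$n,
      ", df = ", x$df, "\n", sep = "")
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se, x$ci)
  print(round(tab, 4))
  cat("sigma^2 (ML) =", signif(x$sigma2, 4),
      " logLik =", round(x$logLik, 3),
      " AICc =", round(x$AICc, 3), "\n")
  invisible(x)
}

#' @export
coef.gls_fit <- function(object, ...) object$coefficients

#' @export
logLik.gls_fit <- function(object, ...) {
  structure(object$logLik, df = object$p + 1, nobs = object$n,
            class = "logLik")
}

#' @export
confint.gls_fit <- function(object, parm, level = 0.95, ...) {
  tq <- stats::qt(1 - (1 - level) / 2, object$df)
  ci <- cbind(object$coefficients - tq * object$se,
              object$coefficients + tq * object$se)
  colnames(ci) <- paste0(c((1 - level) / 2, 1 - (1 - level) / 2) * 100, " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Fit and rank candidate correlation structures by AICc
#'
#' Fits the same regression under white-noise, Brownian-motion and OU
#' (fixed `alpha`) residual covariances and ranks the fits by small-sample
#' corrected AIC. `delta_AICc` is relative to the best model.
#'
#' @inheritParams gls_fit
#' @param tree Ultrametric `phylo` covering the observations; `y` and rows
#'   of `X` must be ordered as `tips`.
#' @param tips Character vector naming the observation order (tree tips).
#' @param structures Character vector of structure kinds to fit.
#' @param alpha Fixed OU rate (default 1).
#' @return An object of class `gls_model_set`: list of `gls_fit`s plus a
#'   ranking table.
#' @export
select_model <- function(y, X, tree, tips, structures = c("WN", "BM", "OU"),
                         alpha = 1, intercept = TRUE) {
  fits <- lapply(structures, function(s) {
    C <- covariance_matrix(tree, correlation_structure(s, alpha = alpha),
                           tips = tips)
    gls_fit(y, X, C, intercept = intercept, structure_name = s)
  })
  names(fits) <- structures
  aicc <- vapply(fits, `[[`, numeric(1), "AICc")
  ord <- order(aicc)
  tab <- data.frame(
    structure = structures[ord],
    logLik = vapply(fits[ord], `[[`, numeric(1), "logLik"),
    AIC = vapply(fits[ord], `[[`, numeric(1), "AIC"),
    AICc = aicc[ord],
    delta_AICc = aicc[ord] - min(aicc),
    row.names = NULL
  )
  structure(list(fits = fits, ranking = tab, best = structures[ord][1]),
            class = "gls_model_set")
}

#' @export
print.gls_model_set <- function(x, ...) {
  cat("GLS correlation-structure comparison (best: ", x$best, ")\n", sep = "")
  print(transform(x$ranking,
                  logLik = round(logLik, 3), AIC = round(AIC, 3),
                  AICc = round(AICc, 3), delta_AICc = round(delta_AICc, 3)))
  invisible(x)
}

# Profile log-likelihood machinery for the intercept-only lambda model.
# Returns a closure factory: given a trait vector, a function of lambda.
# Fast path for ultrametric trees (diag(C) = T): C(lambda) has the same
# eigenvectors as C for every lambda, so one eigendecomposition serves all
# lambda evaluations and all trait vectors (used by the bootstrap null).
.lambda_machinery <- function(C_bm, ultrametric = TRUE) {
  n <- nrow(C_bm)
  if (ultrametric) {
    eg <- eigen(C_bm, symmetric = TRUE)
    Tdepth <- C_bm[1, 1]
    ones <- crossprod(eg$vectors, rep(1, n))
    function(trait) {
      yt <- crossprod(eg$vectors, trait)
      function(lambda) {
        w <- lambda * eg$values + (1 - lambda) * Tdepth
        if (any(w <= 0)) return(-Inf)
        mu <- sum(ones * yt / w) / sum(ones^2 / w)
        r <- yt - mu * ones
        sigma2 <- sum(r^2 / w) / n
        -n / 2 * log(2 * pi * sigma2) - sum(log(w)) / 2 - n / 2
      }
    }
  } else {
    D <- diag(C_bm)
    function(trait) {
      function(lambda) {
        C <- lambda * C_bm
        diag(C) <- D
        U <- tryCatch(chol(C), error = function(e) NULL)
        if (is.null(U)) return(-Inf)
        yt <- backsolve(U, trait, transpose = TRUE)
        ot <- backsolve(U, rep(1, n), transpose = TRUE)
        mu <- sum(ot * yt) / sum(ot^2)
        sigma2 <- sum((yt - mu * ot)^2) / n
        -n / 2 * log(2 * pi * sigma2) - sum(log(diag(U))) - n / 2
      }
    }
  }
}

# ML lambda and the LR statistic against lambda = 0 for one trait vector.
.lambda_lr <- function(prof) {
  opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- rbind(c(0, prof(0)), c(opt$maximum, opt$objective), c(1, prof(1)))
  best <- cand[which.max(cand[, 2]), ]
  list(lambda = best[1], logL = best[2], logL0 = cand[1, 2],
       lr = max(0, 2 * (best[2] - cand[1, 2])))
}

#' Phylogenetic signal: Pagel's lambda and Blomberg's K
#'
#' Pagel's lambda is estimated by maximum likelihood over `[0, 1]` for the
#' intercept-only model, with a likelihood-ratio test against `lambda = 0`
#' (no signal). Because `lambda = 0` sits on the boundary of the parameter
#' space, the chi-squared(1) reference is badly conservative; the default
#' p-value instead comes from a parametric bootstrap. Under the null the LR
#' statistic is pivotal (invariant to the trait's location and scale), so
#' the null distribution is obtained by simulating `n_null` iid standard
#' normal trait vectors on the same tree, which keeps the test calibrated at
#' its nominal level at any sample size. `lambda_p_method = "mixture"` gives
#' the asymptotic 50:50 point-mass/chi-squared(1) boundary mixture instead.
#' Blomberg's K compares the observed to the BM-expected ratio of mean
#' squared error around the phylogenetic mean; its p-value comes from
#' permuting trait values across tips (seeded).
#'
#' @param trait Named numeric vector (names = tip labels), complete.
#' @param tree Ultrametric `phylo` containing all trait names.
#' @param n_perm Number of permutations for the K test (>= 99); use
#'   `statistic = "lambda"` to skip K entirely.
#' @param seed Integer seed for the permutations and the bootstrap null.
#' @param statistic `"both"` (default), `"lambda"` or `"K"`.
#' @param lambda_p_method `"bootstrap"` (default) or `"mixture"`.
#' @param n_null Size of the bootstrap null for the lambda LR test.
#' @return An object of class `phylo_signal` with elements `lambda`,
#'   `lambda_logL`, `lambda_lr`, `lambda_p`, `K`, `K_p`.
#' @export
phylo_signal <- function(trait, tree, n_perm = 999, seed = 1L,
                         statistic = c("both", "lambda", "K"),
                         lambda_p_method = c("bootstrap", "mixture"),
                         n_null = 199L) {
  lambda_p_method <- match.arg(lambda_p_method)
  statistic <- match.arg(statistic)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(trait)))
    stop("'trait' must be named by tip label", call. = FALSE)
  missing <- setdiff(names(trait), tree$tip.label)
  if (length(missing))
    stop("trait names not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(trait)))
    stop("trait contains missing or non-finite values", call. = FALSE)
  if (stats::sd(trait) == 0)
    stop("trait is constant across tips; signal statistics are undefined",
         call. = FALSE)
  if (statistic != "lambda" && n_perm < 99)
    stop("'n_perm' must be at least 99", call. = FALSE)
  n <- length(trait)
  C <- covariance_matrix(tree, "BM", tips = names(trait))
  ultra <- isTRUE(ape::is.ultrametric(tree, option = 2, tol = 1e-6))
  out <- list(lambda = NA_real_, lambda_logL = NA_real_,
              lambda_lr = NA_real_, lambda_p = NA_real_,
              K = NA_real_, K_p = NA_real_, n = n)

  if (statistic %in% c("both", "lambda")) {
    machinery <- .lambda_machinery(C, ultrametric = ultra)
    obs <- .lambda_lr(machinery(unname(trait)))
    out$lambda <- obs$lambda
    out$lambda_logL <- obs$logL
    out$lambda_lr <- obs$lr
    if (lambda_p_method == "mixture") {
      out$lambda_p <- if (obs$lr <= 0) 1 else
        0.5 * stats::pchisq(obs$lr, df = 1, lower.tail = FALSE)
    } else {
      set.seed(as.integer(seed) + 1L)
      null_lr <- vapply(seq_len(n_null), function(i)
        .lambda_lr(machinery(stats::rnorm(n)))$lr, numeric(1))
      out$lambda_p <- (1 + sum(null_lr >= obs$lr)) / (n_null + 1)
    }
  }

  if (statistic %in% c("both", "K")) {
    Cinv <- chol2inv(chol(C))
    ones <- rep(1, n)
    denom_exp <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
    k_stat <- function(y) {
      mu <- sum(Cinv %*% y) / sum(Cinv)
      r <- y - mu
      mse0 <- sum(r^2) / (n - 1)
      mse <- as.numeric(t(r) %*% Cinv %*% r) / (n - 1)
      (mse0 / mse) / denom_exp
    }
    out$K <- k_stat(trait)
    set.seed(as.integer(seed))
    perm <- replicate(n_perm, k_stat(sample(unname(trait))))
    out$K_p <- (1 + sum(perm >= out$K)) / (n_perm + 1)
  }
  structure(out, class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat("Phylogenetic signal (n = ", x$n, " tips)\n", sep = "")
  if (!is.na(x$lambda))
    cat(sprintf("  Pagel's lambda = %.4f  (LR = %.3f, p = %.4g)\n",
                x$lambda, x$lambda_lr, x$lambda_p))
  if (!is.na(x$K))
    cat(sprintf("  Blomberg's K   = %.4f  (permutation p = %.4g)\n",
                x$K, x$K_p))
  invisible(x)
}

#' Phylogenetic scaling regression replica (one response ~ one predictor)
#'
#' Convenience wrapper: log10-transforms the two traits, intersects the
#' trait table with the tree tips (dropped species are reported via a
#' message), fits WN/BM/OU GLS and ranks by AICc. Intercepts are reported on
#' the log10 scale together with their back-transformed (`10^intercept`)
#' values, the form in which power-law prefactors are usually quoted.
#'
#' @param table A trait table (see [read_trait_table()]).
#' @param tree Ultrametric `phylo`.
#' @param response,predictor Trait column names.
#' @param alpha Fixed OU rate.
#' @param structures Structures to compare.
#' @return A `gls_model_set` with an extra `$summary` row for the best model.
#' @export
pgls_scaling <- function(table, tree, response, predictor, alpha = 1,
                         structures = c("WN", "BM", "OU")) {
  keep <- intersect(table$species, tree$tip.label)
  dropped <- setdiff(table$species, keep)
  if (length(dropped))
    message("dropping ", length(dropped),
            " species absent from the tree: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
  if (length(keep) < 4)
    stop("fewer than 4 species shared between table and tree", call. = FALSE)
  tab <- table[match(keep, table$species), , drop = FALSE]
  y <- log10(tab[[response]])
  x <- log10(tab[[predictor]])
  X <- cbind(slope = x)
  ms <- select_model(y, X, tree, tips = keep, structures = structures,
                     alpha = alpha)
  best <- ms$fits[[ms$best]]
  ms$summary <- data.frame(
    response = response, predictor = predictor,
    n = best$n, df = best$df,
    slope = unname(best$coefficients["slope"]),
    slope_lower = best$ci["slope", "lower"],
    slope_upper = best$ci["slope", "upper"],
    intercept_log10 = unname(best$coefficients["(Intercept)"]),
    intercept_backtransformed = 10^unname(best$coefficients["(Intercept)"]),
    model = ms$best,
    AICc = best$AICc,
    delta_AICc_runner_up = ms$ranking$delta_AICc[2]
  )
  ms
}
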