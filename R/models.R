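#' Load an empirical amino-acid substitution model
#'
#' Builds the reversible rate matrix Q from an exchangeability matrix S and
#' stationary frequencies pi: `Q_ij = S_ij * pi_j` (i != j), diagonal set so
#' rows sum to zero, the whole matrix scaled so the expected substitution
#' rate at equilibrium, `-sum(pi_i Q_ii)`, equals 1 — branch lengths are
#' then in expected substitutions per site.
#'
#' `WAG` (Whelan & Goldman 2001) and `JTT` (Jones, Taylor & Thornton 1992)
#' are bundled as PAML-layout `.dat` files; any file in the same layout
#' (lower-triangle exchangeabilities, then 20 frequencies) can be supplied.
#'
#' @param name `"WAG"`, `"JTT"`, or a path to a PAML-layout `.dat` file.
#' @param frequencies `"model"` (the file's frequencies) or a numeric
#'   vector of 20 frequencies (e.g. empirical `+F` counts).
#' @return A `subst_model`: list with `name`, `S`, `pi`, `Q`, plus the
#'   eigendecomposition used by [transition_matrix()].
#' @export
subst_model <- function(name = "WAG", frequencies = "model") {
  path <- if (toupper(name) %in% c("WAG", "JTT")) {
    system.file("extdata", paste0(tolower(name), ".dat"),
                package = "bdmshift", mustWork = TRUE)
  } else {
    if (!file.exists(name)) stop("unknown model / missing file: ", name)
    name
  }
  parsed <- read_paml_dat(path)
  S <- parsed$S
  pi <- if (identical(frequencies, "model")) parsed$pi else {
    if (length(frequencies) != 20L || any(frequencies <= 0)) {
      stop("frequencies must be 20 positive numbers")
    }
    frequencies / sum(frequencies)
  }
  pi <- pi / sum(pi)
  Q <- S * rep(pi, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  structure(
    c(list(name = toupper(basename(name)), S = S, pi = pi, Q = Q),
      rev_eigen(Q, pi)),
    class = "subst_model"
  )
}

# Parse a PAML-style amino-acid model file: 19 lines of lower-triangle
# exchangeabilities followed by a line (or lines) of 20 frequencies.
read_paml_dat <- function(path) {
  toks <- scan(path, what = "character", comment.char = "#", quiet = TRUE)
  nums <- suppressWarnings(as.numeric(toks))
  nums <- nums[!is.na(nums)]
  if (length(nums) < 210L) stop("malformed model file (need 190 + 20 numbers): ", path)
  S <- matrix(0, 20L, 20L, dimnames = list(AA20, AA20))
  k <- 1L
  for (i in 2:20) for (j in 1:(i - 1L)) {
    S[i, j] <- S[j, i] <- nums[k]
    k <- k + 1L
  }
  pi <- nums[191:210]
  if (any(pi <= 0)) stop("stationary frequencies must be positive")
  list(S = S, pi = pi / sum(pi))
}

# Eigendecomposition of the pi-symmetrized rate matrix. For a reversible Q,
# B = diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric with real spectrum, so
# exp(Qt) = diag(1/sqrt(pi)) U exp(Lt) U' diag(sqrt(pi)) is exact and stable.
rev_eigen <- function(Q, pi) {
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  list(eval = eig$values,
       evec_left = eig$vectors * (1 / sp),       # diag(1/sqrt(pi)) U
       evec_right = t(eig$vectors * sp))         # U' diag(sqrt(pi))
}

#' Transition probability matrix P(t) = exp(Q r t)
#'
#' @param model A [subst_model()].
#' @param t Branch length (expected substitutions/site), `>= 0`.
#' @param r Rate multiplier (e.g. a discrete-Gamma category rate), `> 0`.
#' @return A 20x20 row-stochastic matrix.
#' @export
transition_matrix <- function(model, t, r = 1) {
  if (t < 0) stop("branch length must be >= 0")
  if (r <= 0) stop("rate multiplier must be > 0")
  P <- model$evec_left %*% (exp(model$eval * t * r) * model$evec_right)
  P[P < 0] <- 0
  P / rowSums(P)
  }

#' Discrete-Gamma rate categories
#'
#' Approximates Gamma(alpha, alpha)-distributed among-site rate variation
#' (mean 1) by `k` equiprobable categories. With `method = "mean"` each
#' category rate is the exact conditional mean of its quantile bin (computed
#' from the incomplete-gamma identity `E[X; X<b] = F_{alpha+1}(b)` for
#' Gamma(alpha, alpha)), so the category mean is 1 by construction. With
#' `method = "median"` bin medians are used and then rescaled to mean 1.
#'
#' @param alpha Gamma shape parameter, `> 0`.
#' @param k Number of categories, integer `>= 1`.
#' @param method `"mean"` or `"median"`.
#' @return A `gamma_rates`: list with `alpha`, `k`, `rates`, `weights`.
#' @export
discretize_gamma <- function(alpha, k, method = c("mean", "median")) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (k < 1 || k != round(k)) stop("k must be an integer >= 1")
  k <- as.integer(k)
  if (k == 1L) {
    rates <- 1
  } else if (method == "mean") {
    cuts <- stats::qgamma(seq(0, 1, length.out = k + 1L),
                          shape = alpha, rate = alpha)
    cdf1 <- stats::pgamma(cuts, shape = alpha + 1, rate = alpha)
    rates <- k * diff(cdf1)
    rates <- rates / (sum(rates) / k)  # remove residual float error
  } else {
    rates <- stats::qgamma((2 * seq_len(k) - 1) / (2 * k),
                           shape = alpha, rate = alpha)
    rates <- rates / mean(rates)
  }
  structure(list(alpha = alpha, k = k, rates = rates,
                 weights = rep(1 / k, k), method = method),
            class = "gamma_rates")
}

#' Read a score matrix in NCBI matrix text format
#'
#' @param path Path to an NCBI-format matrix (e.g. BLOSUM62). Defaults to
#'   the bundled BLOSUM62.
#' @return A `score_matrix`: symmetric integer 20x20 matrix over [AA20].
#' @export
read_score_matrix <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "blosum62.txt",
                        package = "bdmshift", mustWork = TRUE)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  labs <- vapply(rows, `[`, character(1), 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1L]),
                   numeric(length(header))))
  dimnames(vals) <- list(labs, header)
  missing <- setdiff(AA20, intersect(labs, header))
  if (length(missing)) {
    stop("score matrix lacks standard residues: ", paste(missing, collapse = ","))
  }
  m <- vals[AA20, AA20]
  if (any(abs(m - t(m)) > 0)) stop("score matrix is not symmetric")
  structure(m, class = c("score_matrix", class(m)))
}

#' Rank substitution models by BIC on a fixed topology
#'
#' For each candidate (model, with/without discrete-Gamma) branch lengths
#' (and alpha when Gamma is on) are re-optimized and
#' `BIC = -2 lnL + p log(n)` is computed with `n` = alignment columns and
#' `p` = number of branch lengths plus one for alpha.
#'
#' @param aln A [protein_alignment()].
#' @param phy Tree binding to the alignment.
#' @param candidates List of `list(model =, gamma =, k =)` entries;
#'   default compares WAG and JTT each with and without Gamma.
#' @param alpha_init Starting alpha for Gamma candidates.
#' @param k Gamma category count used when a candidate enables Gamma.
#' @return data.frame (model, gamma, lnL, p, n, BIC, alpha) sorted by BIC.
#' @export
model_select <- function(aln, phy, candidates = NULL, alpha_init = 1.0, k = 2L) {
  if (is.null(candidates)) {
    candidates <- list(
      list(model = "WAG", gamma = FALSE), list(model = "WAG", gamma = TRUE),
      list(model = "JTT", gamma = FALSE), list(model = "JTT", gamma = TRUE)
    )
  }
  if (!length(candidates)) stop("candidate list must be nonempty")
  n <- aln$L
  rows <- lapply(candidates, function(cand) {
    model <- subst_model(cand$model)
    gamma_on <- isTRUE(cand$gamma)
    kk <- if (!is.null(cand$k)) cand$k else k
    fit <- fit_model(aln, phy, model,
                     alpha = if (gamma_on) alpha_init else NA, k = kk,
                     tol = 1e-2, max_rounds = 3L)
    p <- nrow(phy$edge) + if (gamma_on) 1L else 0L
    data.frame(model = cand$model, gamma = gamma_on, lnL = fit$lnL,
               p = p, n = n, BIC = -2 * fit$lnL + p * log(n),
               alpha = if (gamma_on) fit$alpha else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$BIC), , drop = FALSE]
}

# Optimize branch lengths (and alpha if requested) for one model candidate.
fit_model <- function(aln, phy, model, alpha = NA, k = 2L,
                      tol = 1e-4, max_rounds = 5L) {
  gamma_on <- !is.na(alpha)
  rates <- if (gamma_on) discretize_gamma(alpha, k) else discretize_gamma(1, 1L)
  prev <- -Inf
  for (round in seq_len(max_rounds)) {
    opt <- optimize_branch_lengths(aln, phy, model, rates, tol = tol)
    phy <- opt$tree
    lnL <- opt$lnL
    if (gamma_on) {
      f <- function(a) {
        site_log_likelihood(aln, phy, model, discretize_gamma(a, k))$lnL
      }
      oa <- stats::optimize(f, c(0.05, 20), maximum = TRUE, tol = 1e-3)
      alpha <- oa$maximum
      rates <- discretize_gamma(alpha, k)
      lnL <- oa$objective
    }
    if (abs(lnL - prev) < tol) break
    prev <- lnL
  }
  list(tree = phy, lnL = lnL, alpha = alpha, rates = rates)
}
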