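# Sequential hat matrices for a model formula: one per nested model,
# intercept-only first. Used by the RRPP engine.
sequential_hats <- function(formula, data) {
  tt <- stats::terms(formula, data = data)
  labels <- attr(tt, "term.labels")
  hats <- list()
  ranks <- integer(0)
  for (j in 0:length(labels)) {
    f <- if (j == 0) ~1 else stats::reformulate(labels[seq_len(j)])
    X <- model.matrix(f, data = data)
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    hats[[j + 1]] <- tcrossprod(Q)
    ranks[j + 1] <- q$rank
  }
  list(hats = hats, ranks = ranks, labels = labels)
}

rrpp_engine <- function(Y, hats, ranks, labels, n_perm, seed, transform = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  K <- length(labels)
  H_full <- hats[[K + 1]]
  df_res <- n - ranks[K + 1]
  if (df_res <= 0) stop("model is saturated: zero residual degrees of freedom", call. = FALSE)
  ss_of <- function(M, Ym) max(0, sum(Ym * (M %*% Ym)))
  SS_tot <- ss_of(diag(n) - hats[[1]], Y)
  SS_res <- ss_of(diag(n) - H_full, Y)
  ss_floor <- 1e-12 * max(SS_tot, .Machine$double.eps)
  SS_term <- numeric(K)
  df_term <- integer(K)
  for (j in seq_len(K)) {
    SS_term[j] <- ss_of(hats[[j + 1]] - hats[[j]], Y)
    df_term[j] <- ranks[j + 1] - ranks[j]
  }
  degenerate <- SS_tot < .Machine$double.eps * n
  f_of <- function(ssj, dfj, ssr) {
    # a saturated fit (residual SS at numerical zero) has an infinite F
    if (ssr < ss_floor) {
      return(if (ssj > ss_floor) Inf else NaN)
    }
    (ssj / dfj) / (ssr / df_res)
  }
  F_term <- if (degenerate) {
    rep(NA_real_, K)
  } else {
    vapply(seq_len(K), function(j) f_of(SS_term[j], df_term[j], SS_res), numeric(1))
  }
  R2 <- if (degenerate) rep(0, K) else SS_term / SS_tot

  p_perm <- rep(NA_real_, K)
  if (!degenerate && n_perm > 0) {
    set.seed(seed)
    perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
    for (j in seq_len(K)) {
      H_red <- hats[[j]]
      D <- hats[[j + 1]] - H_red
      fit_red <- H_red %*% Y
      res_red <- Y - fit_red
      count <- 0L
      for (p in perms) {
        Yp <- fit_red + res_red[p, , drop = FALSE]
        ssj <- ss_of(D, Yp)
        ssr <- ss_of(diag(n) - H_full, Yp)
        Fp <- f_of(ssj, df_term[j], ssr)
        if (!is.nan(Fp) && Fp >= F_term[j] - 1e-12) count <- count + 1L
      }
      p_perm[j] <- (count + 1) / (n_perm + 1)
    }
  }
  structure(
    list(
      table = tibble::tibble(
        term = c(labels, "Residuals", "Total"),
        df = c(df_term, df_res, n - ranks[1]),
        SS = c(SS_term, SS_res, SS_tot),
        R2 = c(R2, if (degenerate) 0 else SS_res / SS_tot, 1),
        F = c(F_term, NA, NA),
        p_perm = c(p_perm, NA, NA)
      ),
      n_permutations = n_perm, seed = seed, degenerate = degenerate
    ),
    class = "rrpp_anova"
  )
}

#' Procrustes ANOVA with residual-randomization permutation tests
#'
#' Linear models of vectorized shape on factors and covariates, with sums of
#' squares computed over the full coordinate set (trace form) and entered
#' sequentially (type I). Significance comes from randomizing residuals of the
#' reduced model for each term (RRPP): permuted responses are reduced-model
#' fitted values plus shuffled reduced-model residuals, and the p-value is the
#' proportion of permuted F statistics at least as large as the observed one
#' (with the observed permutation counted, so resolution is
#' `1/(n_perm + 1)`).
#'
#' @param shapes n x p response matrix (e.g. from [shape_matrix()]).
#' @param formula right-hand-side formula over columns of `data`, e.g.
#'   `~ log_size + age_category`.
#' @param data data frame of predictors, n rows in the same order as
#'   `shapes`.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutation schedule (default 42).
#' @return an `rrpp_anova` object; `tidy()` returns the ANOVA table.
#' @export
procrustes_anova <- function(shapes, formula, data, n_perm = 1000L, seed = 42L) {
  sh <- sequential_hats(formula, data)
  rrpp_engine(shapes, sh$hats, sh$ranks, sh$labels, n_perm, seed)
}

#' Phylogenetic Procrustes MANOVA
#'
#' Procrustes ANOVA in generalized-least-squares form: response and design are
#' premultiplied by the inverse square root of the Brownian-motion tip
#' covariance implied by the tree, after which the RRPP machinery of
#' [procrustes_anova()] runs on the transformed data (permutations shuffle
#' transformed residuals). On a star tree with equal branch lengths the tip
#' covariance is proportional to the identity and results coincide with the
#' non-phylogenetic ANOVA.
#'
#' @param shapes one row per species (rownames are species names).
#' @param formula,data as in [procrustes_anova()]; `data` must carry a
#'   `species` column matching tip labels.
#' @param tree an [ape::phylo] tree whose tips cover the species.
#' @param n_perm,seed as in [procrustes_anova()].
#' @return an `rrpp_anova` object.
#' @export
pgls_manova <- function(shapes, formula, data, tree, n_perm = 1000L, seed = 42L) {
  shapes <- as.matrix(shapes)
  species <- if ("species" %in% names(data)) data$species else rownames(shapes)
  absent <- setdiff(species, tree$tip.label)
  if (length(absent) > 0) {
    stop("species not in tree: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  C <- ape::vcv(ape::keep.tip(tree, unique(species)))[species, species]
  ec <- eigen(C, symmetric = TRUE)
  if (any(ec$values <= 0)) stop("tip covariance is singular", call. = FALSE)
  P <- ec$vectors %*% diag(1 / sqrt(ec$values)) %*% t(ec$vectors)

  # hats are rebuilt from GLS-transformed design matrices
  tt <- stats::terms(formula, data = data)
  labels <- attr(tt, "term.labels")
  hats <- list()
  ranks <- integer(0)
  for (j in 0:length(labels)) {
    f <- if (j == 0) ~1 else stats::reformulate(labels[seq_len(j)])
    X <- P %*% model.matrix(f, data = data)
    q <- qr(X)
    hats[[j + 1]] <- tcrossprod(qr.Q(q)[, seq_len(q$rank), drop = FALSE])
    ranks[j + 1] <- q$rank
  }
  rrpp_engine(P %*% shapes, hats, ranks, labels, n_perm, seed)
}

#' @export
print.rrpp_anova <- function(x, ...) {
  cat("Procrustes ANOVA (RRPP,", x$n_permutations, "permutations, seed", x$seed, ")\n")
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
tidy.rrpp_anova <- function(x, ...) x$table

#' @export
glance.rrpp_anova <- function(x, ...) {
  terms <- x$table[!(x$table$term %in% c("Residuals", "Total")), ]
  tibble::tibble(
    n_terms = nrow(terms), r_squared = sum(terms$R2),
    n_permutations = x$n_permutations, seed = x$seed
  )
}

#' Spearman rank association
#'
#' Rank correlation with midrank ties and an asymptotic two-sided p-value;
#' the association test used for complexity against skull size.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return a tibble with `rho`, `p_value`, `n` (`rho` is `NA` when either
#'   vector is constant).
#' @export
spearman_assoc <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
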