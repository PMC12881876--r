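#' Maximum-likelihood Brownian-motion ancestral states
#'
#' Joint ML (equivalently generalized-least-squares) estimates of a continuous
#' trait at the internal nodes of a rooted tree under Brownian motion: the
#' states minimize the sum over edges of squared parent-child differences
#' weighted by inverse branch length. The solution is the unique solution of a
#' sparse linear system, so the estimate is deterministic; polytomies are
#' handled natively. The rate estimate is the ML rate given the states,
#' `sigma2 = sum(diff^2 / length) / n_edges`.
#'
#' Internal-node estimates always lie within the range of the tip values, and
#' the whole estimate is shift- and scale-equivariant in the tips.
#'
#' @param tree a rooted [ape::phylo] tree with positive branch lengths.
#' @param tip_values named numeric vector covering all tips.
#' @return a `bm_asr` object with `node_estimates` (tibble over all nodes,
#'   tips included), `sigma2` and `log_likelihood`.
#' @export
asr_bm_ml <- function(tree, tip_values) {
  validate_tree(tree)
  n_tip <- length(tree$tip.label)
  if (!all(tree$tip.label %in% names(tip_values))) {
    stop(
      "tip values missing for: ",
      paste(setdiff(tree$tip.label, names(tip_values)), collapse = ", "),
      call. = FALSE
    )
  }
  x_tip <- tip_values[tree$tip.label]
  n_node <- tree$Nnode
  edges <- tree$edge
  bl <- tree$edge.length
  if (any(bl == 0)) {
    warning("zero-length branches replaced by a small positive length", call. = FALSE)
    bl[bl == 0] <- min(bl[bl > 0], 1) * 1e-8
  }
  w <- 1 / bl
  # unknowns: internal nodes (ids n_tip+1 .. n_tip+n_node)
  A <- matrix(0, n_node, n_node)
  b <- numeric(n_node)
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1] - n_tip
    ch <- edges[e, 2]
    A[p, p] <- A[p, p] + w[e]
    if (ch > n_tip) {
      c2 <- ch - n_tip
      A[p, c2] <- A[p, c2] - w[e]
      A[c2, p] <- A[c2, p] - w[e]
      A[c2, c2] <- A[c2, c2] + w[e]
    } else {
      b[p] <- b[p] + w[e] * x_tip[ch]
    }
  }
  x_int <- drop(solve(A, b))
  states <- c(x_tip, x_int)
  d <- states[edges[, 1]] - states[edges[, 2]]
  sigma2 <- sum(d^2 * w) / nrow(edges)
  ll <- if (sigma2 > 0) sum(dnorm(d, 0, sqrt(sigma2 * bl), log = TRUE)) else Inf
  structure(
    list(
      node_estimates = tibble::tibble(
        node = seq_along(states),
        label = c(tree$tip.label, rep(NA_character_, n_node)),
        estimate = unname(states),
        is_tip = seq_along(states) <= n_tip
      ),
      sigma2 = sigma2, log_likelihood = ll, tree = tree
    ),
    class = "bm_asr"
  )
}

#' @export
print.bm_asr <- function(x, ...) {
  cat(
    "Brownian-motion ancestral states:", sum(x$node_estimates$is_tip), "tips,",
    sum(!x$node_estimates$is_tip), "internal nodes; sigma2 =",
    signif(x$sigma2, 4), "\n"
  )
  invisible(x)
}

#' @export
tidy.bm_asr <- function(x, ...) x$node_estimates

#' @export
glance.bm_asr <- function(x, ...) {
  tibble::tibble(
    sigma2 = x$sigma2, log_likelihood = x$log_likelihood,
    root_estimate = x$node_estimates$estimate[sum(x$node_estimates$is_tip) + 1]
  )
}

#' @export
autoplot.bm_asr <- function(object, ...) {
  depths <- ape::node.depth.edgelength(object$tree)
  df <- object$node_estimates
  df$age <- max(depths) - depths
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$age, y = .data$estimate,
    shape = .data$is_tip
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "node age (tree depth units)", y = "estimated state") +
    ggplot2::theme_minimal()
}

#' Ancestral value of a clade
#'
#' Reads the estimated state at the most recent common ancestor of a tip set;
#' the set must be monophyletic in the tree.
#'
#' @param estimate a `bm_asr` object.
#' @param clade_tips character vector of tip labels (a single tip returns its
#'   observed value; all tips return the root estimate).
#' @return the estimated state (scalar).
#' @export
clade_ancestor_value <- function(estimate, clade_tips) {
  tree <- estimate$tree
  absent <- setdiff(clade_tips, tree$tip.label)
  if (length(absent) > 0) {
    stop("tip(s) not in tree: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  if (length(clade_tips) == 1) {
    return(estimate$node_estimates$estimate[match(clade_tips, tree$tip.label)])
  }
  node <- ape::getMRCA(tree, clade_tips)
  desc <- ape::extract.clade(tree, node)$tip.label
  intruders <- setdiff(desc, clade_tips)
  if (length(intruders) > 0) {
    stop(
      "clade is not monophyletic; intruding tip(s): ",
      paste(intruders, collapse = ", "),
      call. = FALSE
    )
  }
  estimate$node_estimates$estimate[node]
}

#' Simulation-based phylogenetic ANOVA
#'
#' One-way ANOVA of a species trait across groups where the null distribution
#' of the F statistic accounts for phylogenetic covariance: the trait is
#' simulated `n_sim` times under Brownian motion on the tree at the rate
#' estimated from the observed tips (REML, from phylogenetically independent
#' contrasts), F is recomputed for each simulation, and the p-value is the
#' proportion of simulated F at least as large as the observed (with the
#' observed counted). On a star tree the null converges to the conventional
#' permutation ANOVA.
#'
#' @param tip_values named numeric vector over tips.
#' @param groups factor over the same species (>= 2 levels).
#' @param tree an [ape::phylo] tree.
#' @param n_sim Brownian-motion simulations (default 1000).
#' @param seed RNG seed (default 42).
#' @return a `phylo_anova` object with the observed F, simulation p-value and
#'   rate.
#' @export
phyl_anova <- function(tip_values, groups, tree, n_sim = 1000L, seed = 42L) {
  validate_tree(tree)
  x <- tip_values[tree$tip.label]
  if (anyNA(x)) stop("tip values missing for some tips", call. = FALSE)
  if (!is.null(names(groups))) {
    groups <- groups[tree$tip.label]
  } else if (length(groups) != length(x)) {
    stop("groups must be named by species or ordered like the tips", call. = FALSE)
  }
  groups <- factor(as.character(groups))
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups", call. = FALSE)
  f_stat <- function(v) {
    fit <- anova(lm(v ~ groups))
    fit$`F value`[1]
  }
  F_obs <- f_stat(x)
  sigma2 <- mean(ape::pic(x, ape::multi2di(tree))^2) # REML rate from contrasts
  C <- ape::vcv(tree)
  L <- chol(C)
  set.seed(seed)
  Z <- matrix(rnorm(length(x) * n_sim), ncol = n_sim)
  sims <- sqrt(sigma2) * crossprod(L, Z)
  F_sim <- apply(sims, 2, f_stat)
  p <- (sum(F_sim >= F_obs) + 1) / (n_sim + 1)
  structure(
    list(
      table = tibble::tibble(
        term = "groups", F = F_obs, p_sim = p,
        sigma2 = sigma2, n_sim = n_sim
      ),
      F = F_obs, p_value = p, sigma2 = sigma2, n_sim = n_sim, seed = seed
    ),
    class = "phylo_anova"
  )
}

#' @export
print.phylo_anova <- function(x, ...) {
  cat(
    "Phylogenetic ANOVA: F =", signif(x$F, 4), ", p =", signif(x$p_value, 4),
    "(", x$n_sim, "BM simulations, seed", x$seed, ")\n"
  )
  invisible(x)
}

#' @export
tidy.phylo_anova <- function(x, ...) x$table

#' @export
glance.phylo_anova <- function(x, ...) {
  tibble::tibble(F = x$F, p_value = x$p_value, sigma2 = x$sigma2, n_sim = x$n_sim)
}

#' Write ancestral estimates as an annotated newick tree
#'
#' Node estimates become node labels (rounded to `digits`), so the annotated
#' tree can be rendered by any newick-aware viewer.
#'
#' @param estimate a `bm_asr` object.
#' @param path output newick path.
#' @param digits label precision (default 4).
#' @return `path` invisibly.
#' @export
write_asr_tree <- function(estimate, path, digits = 4) {
  tree <- estimate$tree
  est <- estimate$node_estimates
  tree$node.label <- formatC(est$estimate[!est$is_tip], digits = digits, format = "g")
  ape::write.tree(tree, file = path)
  invisible(path)
}
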