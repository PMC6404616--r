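#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` annotated genes when drawing a
#' query of size `n` without replacement from a universe of `N` genes of
#' which `K` are annotated:
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(n,K)}
#'   \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' The tail includes the observed count (the standard over-representation
#' convention). Terms are accumulated in log space (log-binomials +
#' log-sum-exp) so the sum is stable for genome-scale `N`.
#'
#' @param k Observed overlap (query and annotated set).
#' @param n Query-set size.
#' @param K Annotated genes in the universe.
#' @param N Universe size.
#' @return `P(X >= k)`; exactly 1 when `k` is at or below the smallest
#'   possible overlap, 0 when `k` exceeds `min(n, K)`.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  vapply(k, function(ki) hyper_tail_one(ki, n, K, N), numeric(1))
}

hyper_tail_one <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || n > N || K > N ||
      any(c(k, n, K, N) != round(c(k, n, K, N)))) {
    ps_abort("hypergeometric inputs must be integers with n <= N, K <= N, k >= 0",
             "value_error")
  }
  hi <- min(n, K)
  if (k > hi) return(0)
  lo <- max(0, n + K - N)  # smallest achievable overlap
  if (k <= lo) return(1)
  i <- k:hi
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logp)
  min(1, exp(m + log(sum(exp(logp - m)))))
}

#' Multiple-testing correction
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up with
#' monotonicity enforcement.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @param method `"bonferroni"` or `"bh"`.
#' @return Corrected p-values, same length and order as `p`.
#' @export
correct_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    ps_abort("p-values must lie in (0, 1]", "value_error")
  }
  stats::p.adjust(p, method = c(bonferroni = "bonferroni", bh = "BH")[method])
}

#' Gene-set over-representation analysis
#'
#' Tests every term of the annotation's term map, and every binary flag,
#' for over-representation in the query set by the upper-tail
#' hypergeometric probability [hypergeom_upper_tail()], with
#' multiple-testing correction applied within each family (terms and flags
#' are corrected separately). Query genes outside the universe are
#' intersected away with a warning.
#'
#' @param query Character vector of query genes (e.g. the sensitive set of
#'   one compound).
#' @param annotation A [gene_annotation()]. The choice of universe (screened
#'   genes vs whole genome) is the caller's: pass the universe you want to
#'   condition on.
#' @param alpha Significance level applied to corrected p-values
#'   (significant when `p_corrected < alpha`).
#' @param method Correction method, see [correct_pvalues()].
#' @return data.frame of class `enrichment_result`, sorted by raw p
#'   ascending (ties by term id): columns `term`, `name`, `family`
#'   (`"term"` or `"flag"`), `k`, `n`, `K`, `N`, `p_raw`, `p_corrected`,
#'   `method`, `significant`. Attribute `alpha` records the reference
#'   threshold.
#' @export
enrich_gene_sets <- function(query, annotation, alpha = 0.05,
                             method = "bonferroni") {
  if (!inherits(annotation, "gene_annotation")) {
    ps_abort("annotation must be a gene_annotation", "config_error")
  }
  universe <- annotation$universe
  if (!length(universe)) ps_abort("empty gene universe", "config_error")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    ps_warn(sprintf("%d query gene(s) outside the universe were dropped",
                    length(outside)), "query_outside_universe")
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)

  one_family <- function(ids, names_, member_sets, family) {
    if (!length(ids)) return(NULL)
    K <- vapply(member_sets, length, integer(1))
    k <- vapply(member_sets, function(g) length(intersect(g, query)),
                integer(1))
    p <- vapply(seq_along(ids), function(i) {
      hyper_tail_one(k[i], n, K[i], N)
    }, numeric(1))
    data.frame(term = ids, name = names_, family = family,
               k = k, n = n, K = K, N = N, p_raw = p,
               row.names = NULL)
  }

  tm <- annotation$term_map
  res <- one_family(names(tm),
                    vapply(tm, function(t) t$name, character(1)),
                    lapply(tm, function(t) t$genes), "term")
  if (!is.null(annotation$flags)) {
    labels <- setdiff(names(annotation$flags), "gene")
    sets <- lapply(labels, function(lb) {
      annotation$flags$gene[annotation$flags[[lb]] == 1]
    })
    res <- rbind(res, one_family(labels, labels, sets, "flag"))
  }
  if (is.null(res) || !nrow(res)) {
    out <- data.frame(term = character(0), name = character(0),
                      family = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_raw = numeric(0),
                      p_corrected = numeric(0), method = character(0),
                      significant = logical(0))
    class(out) <- c("enrichment_result", "data.frame")
    attr(out, "alpha") <- alpha
    return(out)
  }
  res$p_corrected <- NA_real_
  for (fam in unique(res$family)) {
    sel <- res$family == fam
    res$p_corrected[sel] <- correct_pvalues(res$p_raw[sel], method)
  }
  res$method <- method
  res$significant <- res$p_corrected < alpha
  res <- res[order(res$p_raw, res$term), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  attr(res, "alpha") <- alpha
  res
}

#' Radial bubble layout for significant gene-set terms
#'
#' Lays significant terms out as circles around a center label: each term's
#' circle radius and its radial distance from the center are the same
#' monotone linear function of its gene count (up to the two scale
#' constants), and circles are color-binned by corrected p-value. Angles
#' are assigned by rank order of the gene count around the circle, then
#' nudged by an angular-repulsion pass so no two circle boundaries overlap.
#'
#' @param results An [enrich_gene_sets()] result; every row must be
#'   significant at its `alpha`.
#' @param radius_scale Circle radius per gene (default 0.6).
#' @param dist_scale Radial distance per gene (default 3).
#' @param p_breaks Bin edges for the p-value color scale.
#' @return data.frame of class `bubble_layout` with columns `term`, `k`,
#'   `radius`, `radial_distance`, `angle` (radians), `x`, `y`,
#'   `p_corrected`, `color_bin`. Empty input gives an empty (valid) layout.
#' @export
bubble_layout <- function(results, radius_scale = 0.6, dist_scale = 3,
                          p_breaks = c(0, 1e-4, 1e-3, 1e-2, 0.05)) {
  if (nrow(results) == 0) {
    out <- data.frame(term = character(0), k = integer(0),
                      radius = numeric(0), radial_distance = numeric(0),
                      angle = numeric(0), x = numeric(0), y = numeric(0),
                      p_corrected = numeric(0),
                      color_bin = character(0))
    class(out) <- c("bubble_layout", "data.frame")
    return(out)
  }
  if (!all(results$significant)) {
    ps_abort("bubble_layout expects only significant results", "value_error")
  }
  r <- results[order(results$k, results$term), ]
  m <- nrow(r)
  radius <- radius_scale * r$k
  dist <- dist_scale * r$k
  angle <- 2 * pi * (seq_len(m) - 1) / m

  # angular repulsion: push apart any overlapping pair, keeping distances
  # (and hence the count-proportionality invariant) fixed
  for (iter in seq_len(400)) {
    x <- dist * cos(angle); y <- dist * sin(angle)
    moved <- FALSE
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      gap <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) -
        (radius[i] + radius[j])
      if (gap < 0) {
        step <- 0.03 * pi
        if (angle[i] <= angle[j]) {
          angle[i] <- angle[i] - step; angle[j] <- angle[j] + step
        } else {
          angle[i] <- angle[i] + step; angle[j] <- angle[j] - step
        }
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  bins <- cut(r$p_corrected, breaks = p_breaks, include.lowest = TRUE)
  out <- data.frame(term = r$term, k = r$k, radius = radius,
                    radial_distance = dist, angle = angle %% (2 * pi),
                    x = dist * cos(angle), y = dist * sin(angle),
                    p_corrected = r$p_corrected,
                    color_bin = as.character(bins))
  class(out) <- c("bubble_layout", "data.frame")
  out
}

#' Plot a bubble layout
#'
#' Draws the radial bubble chart: one circle per significant term, sized and
#' placed by gene count, colored by p-value bin, around a center label.
#'
#' @param layout A [bubble_layout()] result.
#' @param center_label Text placed at the center.
#' @param path Optional output path (via [ggplot2::ggsave()]).
#' @return The ggplot object, invisibly.
#' @export
plot_bubble <- function(layout, center_label = "query", path = NULL) {
  circle_poly <- function(x0, y0, r, id, bin) {
    th <- seq(0, 2 * pi, length.out = 60)
    data.frame(x = x0 + r * cos(th), y = y0 + r * sin(th),
               id = id, color_bin = bin)
  }
  polys <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    circle_poly(layout$x[i], layout$y[i], layout$radius[i],
                layout$term[i], layout$color_bin[i])
  }))
  gp <- ggplot2::ggplot() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void() +
    ggplot2::annotate("text", x = 0, y = 0, label = center_label)
  if (!is.null(polys)) {
    gp <- gp + ggplot2::geom_polygon(
      data = polys,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$id,
                   fill = .data$color_bin),
      alpha = 0.8, color = "grey30") +
      ggplot2::scale_fill_brewer(palette = "YlOrRd", direction = -1,
                                 name = "corrected p")
  }
  if (!is.null(path)) ggplot2::ggsave(path, gp, width = 6, height = 6)
  invisible(gp)
}
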