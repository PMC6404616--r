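#' Cross-compound overlap accounting for sensitive-strain sets
#'
#' Exact set arithmetic over the per-compound sensitive sets: pairwise
#' intersection counts (reported inclusive of higher-order intersections,
#' the convention under which unique counts follow by inclusion-exclusion),
#' the triple intersection for three compounds, the union, and per-compound
#' unique counts with their fractions of the union.
#'
#' @param sets Named list of character vectors (compound -> sensitive gene
#'   set). Any number of compounds is supported; the classic screen design
#'   has two or three.
#' @return An object of class `overlap_summary`: list with `sizes`,
#'   `pairwise` (named symmetric matrix of intersection counts, inclusive),
#'   `triple` (for exactly 3 sets, else `NA`), `union_size`, `unique_counts`
#'   and `unique_fractions` (of the union).
#' @export
overlap_analysis <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  sets <- lapply(sets, unique)
  nms <- names(sets)
  k <- length(sets)
  sizes <- vapply(sets, length, integer(1))
  pairwise <- matrix(NA_integer_, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  }
  triple <- if (k == 3) length(Reduce(intersect, sets)) else NA_integer_
  all_genes <- unique(unlist(sets))
  unique_counts <- vapply(seq_len(k), function(i) {
    length(setdiff(sets[[i]], unlist(sets[-i])))
  }, integer(1))
  names(unique_counts) <- nms
  out <- structure(
    list(sizes = sizes, pairwise = pairwise, triple = triple,
         union_size = length(all_genes),
         unique_counts = unique_counts,
         unique_fractions = unique_counts / length(all_genes)),
    class = "overlap_summary"
  )
  check_inclusion_exclusion(out)
  out
}

#' Overlap accounting from printed marginal counts
#'
#' Reconstructs the overlap summary when only published counts are
#' available, not the underlying gene lists. For three sets, supply the set
#' sizes, whatever pairwise intersection counts are known (inclusive of the
#' triple) and the triple count; each set's unique count follows by
#' inclusion-exclusion (`size - sum of its pairwise overlaps + triple`) and
#' is `NA` when one of its pairwise counts is unknown. For two sets, supply
#' the sizes plus either the intersection or one unique count. Quantities
#' that the supplied counts do not determine are reported as `NA`, never
#' guessed.
#'
#' @param sizes Named integer vector of set sizes.
#' @param pairwise Named symmetric matrix (or `NULL`) of pairwise
#'   intersection counts, inclusive of the triple; `NA` where unknown.
#' @param triple Triple intersection count (3-set case).
#' @param unique_counts Optional named vector of known unique counts (used
#'   in the 2-set case to derive the intersection).
#' @return An `overlap_summary` (some fields possibly `NA`).
#' @export
overlap_from_counts <- function(sizes, pairwise = NULL, triple = NA_integer_,
                                unique_counts = NULL) {
  nms <- names(sizes)
  k <- length(sizes)
  pw <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  diag(pw) <- sizes
  if (!is.null(pairwise)) {
    for (i in rownames(pairwise)) for (j in colnames(pairwise)) {
      if (i != j && !is.na(pairwise[i, j])) {
        pw[i, j] <- pw[j, i] <- pairwise[i, j]
      }
    }
  }
  if (k == 2) {
    i12 <- pw[1, 2]
    if (is.na(i12) && !is.null(unique_counts)) {
      nm <- names(unique_counts)[1]
      i12 <- sizes[[nm]] - unique_counts[[1]]
      pw[1, 2] <- pw[2, 1] <- i12
    }
    uniq <- c(sizes[[1]] - i12, sizes[[2]] - i12)
    union_size <- sizes[[1]] + sizes[[2]] - i12
    triple <- NA_integer_
  } else if (k == 3) {
    uniq <- vapply(seq_len(k), function(i) {
      others <- setdiff(seq_len(k), i)
      ov <- pw[i, others]
      if (any(is.na(ov)) || is.na(triple)) return(NA_real_)
      sizes[[i]] - sum(ov) + triple
    }, numeric(1))
    union_size <- if (any(is.na(pw[upper.tri(pw)])) || is.na(triple)) {
      NA_real_
    } else {
      sum(sizes) - sum(pw[upper.tri(pw)]) + triple
    }
  } else {
    ps_abort("overlap_from_counts supports 2 or 3 sets", "config_error")
  }
  names(uniq) <- nms
  structure(
    list(sizes = sizes, pairwise = pw, triple = triple,
         union_size = union_size, unique_counts = uniq,
         unique_fractions = uniq / union_size),
    class = "overlap_summary"
  )
}

# Inclusion-exclusion consistency check, applied to every summary built
# from explicit sets.
check_inclusion_exclusion <- function(x) {
  k <- length(x$sizes)
  if (k == 3 && !is.na(x$triple) && !any(is.na(x$pairwise))) {
    lhs <- x$union_size
    rhs <- sum(x$sizes) - sum(x$pairwise[upper.tri(x$pairwise)]) + x$triple
    if (lhs != rhs) {
      ps_abort(sprintf(
        "inclusion-exclusion violated: union %d != %d", lhs, rhs),
        "value_error")
    }
  }
  invisible(x)
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("overlap_summary\n sizes: ",
      paste(sprintf("%s=%s", names(x$sizes), x$sizes), collapse = ", "),
      "\n union: ", x$union_size,
      if (length(x$sizes) == 3) sprintf(" (triple = %s)", x$triple) else "",
      "\n unique: ",
      paste(sprintf("%s=%s", names(x$unique_counts), x$unique_counts),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Overlap summary as a tidy table
#'
#' @param x An `overlap_summary`.
#' @param ... Unused.
#' @return data.frame with one row per compound: size, unique count and
#'   unique fraction of the union.
#' @export
as.data.frame.overlap_summary <- function(x, ...) {
  data.frame(compound = names(x$sizes),
             size = as.numeric(x$sizes),
             unique_count = as.numeric(x$unique_counts),
             unique_fraction = as.numeric(x$unique_fractions),
             union_size = x$union_size,
             row.names = NULL)
}

#' Build a log2 GSV profile matrix
#'
#' Converts growth scores into the matrix the clustering stage consumes:
#' entries are `log2(max(gsv, floor))`, so the sensitivity cutoff 0.5 maps
#' to -1 and the resistance cutoff 2.0 to +1 (symmetric treatment of the two
#' call directions). Strains with any undefined GSV are dropped with a
#' message, never silently.
#'
#' @param scores data.frame with columns `strain`, a condition column
#'   (`compound` by default) and `gsv` (e.g. [score_screen()] output).
#' @param floor Positive floor applied before the log (default 0.05) so a
#'   fully inhibited strain maps to a finite value.
#' @param condition_col Name of the condition column.
#' @return Numeric matrix (strains x conditions) of class `profile_matrix`
#'   with attribute `floor`.
#' @export
build_profile_matrix <- function(scores, floor = 0.05,
                                 condition_col = "compound") {
  check_scalar_number(floor, "floor", min = 0, strict_min = TRUE)
  if (!nrow(scores)) ps_abort("no scores to convert", "empty_matrix_error")
  strains <- unique(scores$strain)
  conds <- unique(scores[[condition_col]])
  m <- matrix(NA_real_, length(strains), length(conds),
              dimnames = list(strains, conds))
  m[cbind(match(scores$strain, strains),
          match(scores[[condition_col]], conds))] <- scores$gsv
  incomplete <- rowSums(is.na(m)) > 0
  if (any(incomplete)) {
    message(sprintf("build_profile_matrix: dropping %d strain(s) with undefined GSVs: %s",
                    sum(incomplete),
                    paste(utils::head(rownames(m)[incomplete], 5),
                          collapse = ", ")))
    m <- m[!incomplete, , drop = FALSE]
  }
  if (!nrow(m)) ps_abort("no complete profiles left", "empty_matrix_error")
  m <- log2(pmax(m, floor))
  structure(m, class = c("profile_matrix", "matrix"), floor = floor)
}

#' Agglomerative hierarchical clustering of fitness profiles
#'
#' Average-linkage clustering on Euclidean distances by default (the classic
#' expression-profile clustering recipe), via [stats::hclust()]. The result
#' records the merge tree, heights and leaf order and can be exported as a
#' Newick tree.
#'
#' @param mat Numeric matrix with >= 2 rows and no missing entries (e.g. a
#'   [build_profile_matrix()] result).
#' @param metric Distance metric, passed to [stats::dist()].
#' @param linkage Linkage method, passed to [stats::hclust()].
#' @return An object of class `cluster_result`: list with `merge`, `height`,
#'   `order`, `labels`, `metric`, `linkage` and the underlying `hclust`
#'   object.
#' @export
hierarchical_cluster <- function(mat, metric = "euclidean",
                                 linkage = "average") {
  m <- unclass(mat)
  if (is.null(dim(m)) || nrow(m) < 2) {
    ps_abort("clustering needs at least two profile rows", "value_error")
  }
  if (any(!is.finite(m))) {
    ps_abort("profile matrix contains non-finite entries", "value_error")
  }
  hc <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  if (is.unsorted(hc$height)) {
    ps_abort("merge heights are not nondecreasing", "value_error")
  }
  structure(
    list(merge = hc$merge, height = hc$height, order = hc$order,
         labels = hc$labels, metric = metric, linkage = linkage,
         hclust = hc),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d leaves, %s distance, %s linkage\n",
              length(x$order), x$metric, x$linkage))
  invisible(x)
}

#' Write a cluster tree as Newick text
#'
#' @param cluster A [hierarchical_cluster()] result.
#' @param path Output path for the Newick file.
#' @export
write_cluster_newick <- function(cluster, path) {
  ape::write.tree(ape::as.phylo(cluster$hclust), file = path)
  invisible(path)
}

#' Heatmap of a clustered profile matrix
#'
#' Red/blue encoding of log2 GSVs: red below 0 (sensitive), blue above 0
#' (resistant), white at wild-type-like growth. Rows are ordered by the
#' cluster leaf order when a cluster result is supplied.
#'
#' @param mat A `profile_matrix`.
#' @param cluster Optional [hierarchical_cluster()] result for row ordering.
#' @param path Optional output path (PNG/SVG/PDF via [ggplot2::ggsave()]).
#' @return The ggplot object, invisibly.
#' @export
plot_profile_heatmap <- function(mat, cluster = NULL, path = NULL) {
  m <- unclass(mat)
  if (!is.null(cluster)) m <- m[cluster$order, , drop = FALSE]
  df <- data.frame(
    strain = factor(rep(rownames(m), ncol(m)), levels = rev(rownames(m))),
    condition = rep(colnames(m), each = nrow(m)),
    log2_gsv = as.vector(m)
  )
  gp <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$condition, y = .data$strain, fill = .data$log2_gsv)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "red3", mid = "white",
                                  high = "blue3", midpoint = 0,
                                  name = "log2 GSV") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, gp, width = 5,
                    height = max(2, 0.15 * nrow(m) + 1), limitsize = FALSE)
  }
  invisible(gp)
}
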