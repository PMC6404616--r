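#' Simulate a gene universe, query set and gene-set terms with planted signal
#'
#' Builds a synthetic enrichment problem with known truth: a gene universe,
#' a query set (e.g. the sensitive-strain gene list a screen would produce),
#' and `n_terms` gene sets. A term with planted fold \eqn{f} is constructed
#' so that its expected overlap with the query is \eqn{f} times the
#' hypergeometric expectation \eqn{n K / N}; terms with fold 1 are sampled
#' uniformly from the universe and are therefore exact draws from the
#' enrichment null.
#'
#' @param n_genes Universe size.
#' @param n_terms Number of gene-set terms (0 gives an empty term map).
#' @param term_size_range Length-2 integer interval of term sizes, drawn
#'   uniformly.
#' @param query_size Size of the query gene set.
#' @param planted Named numeric vector of enrichment folds (>= 1), named by
#'   term index or term id (`"T0003"`); terms not listed have fold 1.
#' @param flag_rates Named numeric vector of per-gene Bernoulli rates for
#'   binary flags; set to `NULL` for no flags.
#' @param gene_ids Optional explicit universe (overrides `n_genes`).
#' @param query Optional explicit query set (overrides `query_size`).
#' @param seed Integer seed.
#' @return A list with `annotation` ([gene_annotation()]), `query`
#'   (character vector) and `truth` (data.frame: term, size, fold,
#'   planted_overlap).
#' @export
simulate_annotation_universe <- function(n_genes = 2000, n_terms = 100,
                                         term_size_range = c(20, 100),
                                         query_size = 300,
                                         planted = NULL,
                                         flag_rates = c(human_ortholog = 0.3,
                                                        disease_associated = 0.1,
                                                        kinase = 0.05,
                                                        essential = 0.15),
                                         gene_ids = NULL, query = NULL,
                                         seed = 1L) {
  check_scalar_number(n_terms, "n_terms", min = 0)
  if (!is.null(planted) && any(planted < 1)) {
    ps_abort("planted folds must be >= 1", "config_error")
  }
  if (max(term_size_range) > (if (is.null(gene_ids)) n_genes
                              else length(gene_ids))) {
    ps_abort("term size exceeds the universe size", "config_error")
  }
  with_seed(seed, {
    universe <- gene_ids %||% sprintf("gene%05d", seq_len(n_genes))
    N <- length(universe)
    query <- query %||% sample(universe, query_size)
    n <- length(query)
    non_query <- setdiff(universe, query)

    term_ids <- if (n_terms > 0) sprintf("T%04d", seq_len(n_terms))
                else character(0)
    folds <- stats::setNames(rep(1, n_terms), term_ids)
    if (!is.null(planted) && n_terms > 0) {
      keys <- names(planted)
      idx <- ifelse(keys %in% term_ids, keys,
                    term_ids[suppressWarnings(as.integer(keys))])
      if (anyNA(idx)) ps_abort("planted term not found", "config_error")
      folds[idx] <- planted
    }

    term_map <- list()
    truth <- data.frame(term = character(0), size = integer(0),
                        fold = numeric(0), planted_overlap = integer(0))
    for (id in term_ids) {
      K <- if (term_size_range[1] == term_size_range[2]) term_size_range[1]
           else sample(seq(term_size_range[1], term_size_range[2]), 1)
      f <- folds[[id]]
      if (f == 1) {
        genes <- sample(universe, K)
      } else {
        m <- round(min(f * n * K / N, min(K, n)))
        genes <- c(sample(query, m), sample(non_query, K - m))
      }
      term_map[[id]] <- list(name = sprintf("synthetic process %s", id),
                             genes = genes)
      truth <- rbind(truth, data.frame(
        term = id, size = K, fold = f,
        planted_overlap = length(intersect(genes, query))))
    }

    flags <- NULL
    if (!is.null(flag_rates)) {
      flags <- data.frame(gene = universe)
      for (lb in names(flag_rates)) {
        flags[[lb]] <- stats::rbinom(N, 1, flag_rates[[lb]])
      }
    }
    list(annotation = gene_annotation(universe, flags = flags,
                                      term_map = term_map),
         query = query, truth = truth)
  })
}
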