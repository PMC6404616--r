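#' Gene annotation: universe, binary flags and gene-set terms
#'
#' Container for the enrichment inputs: the gene universe (all genes the
#' screen could have detected), optional binary per-gene flags (e.g.
#' `human_ortholog`, `disease_associated`, `kinase`, `essential`), and a
#' map of gene-set terms (GO-like biological-process categories).
#'
#' @param universe Character vector of gene identifiers.
#' @param flags Optional data.frame with column `gene` plus one 0/1 column
#'   per flag label.
#' @param term_map Optional named list; each element is a list with `name`
#'   (description) and `genes` (character vector of members). Every member
#'   must be in the universe.
#' @param flag_vocabulary Allowed flag labels; defaults to the labels present.
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(universe, flags = NULL, term_map = list(),
                            flag_vocabulary = NULL) {
  universe <- unique(as.character(universe))
  if (!length(universe)) ps_abort("empty gene universe", "config_error")
  if (!is.null(flags)) {
    if (!"gene" %in% names(flags)) {
      ps_abort("flags table must have a 'gene' column", "config_error")
    }
    labels <- setdiff(names(flags), "gene")
    vocab <- flag_vocabulary %||% labels
    extra <- setdiff(labels, vocab)
    if (length(extra)) {
      ps_abort(sprintf("flag label(s) outside the declared vocabulary: %s",
                       paste(extra, collapse = ", ")), "config_error")
    }
    for (lb in labels) {
      if (!all(flags[[lb]] %in% c(0, 1))) {
        ps_abort(sprintf("flag column '%s' must be 0/1", lb), "parse_error")
      }
    }
    if (!all(flags$gene %in% universe)) {
      ps_abort("flags table contains genes outside the universe",
               "config_error")
    }
  }
  for (id in names(term_map)) {
    genes <- term_map[[id]]$genes
    outside <- setdiff(genes, universe)
    if (length(outside)) {
      ps_abort(sprintf("term '%s' has member(s) outside the universe: %s",
                       id, paste(utils::head(outside, 3), collapse = ", ")),
               "config_error")
    }
  }
  structure(list(universe = universe, flags = flags, term_map = term_map),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes, %d terms, %d flag label(s)\n",
              length(x$universe), length(x$term_map),
              if (is.null(x$flags)) 0L else ncol(x$flags) - 1L))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' GMT is the conventional tab-separated gene-set format: one set per line,
#' fields `term_id`, `description`, then one or more member genes. Repeated
#' members within a line are deduplicated.
#'
#' @param path Path to the GMT file.
#' @return A named list (term id -> list(name, genes)) suitable as the
#'   `term_map` of [gene_annotation()].
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) {
    ps_abort(sprintf("gene-set file not found: %s", path), "io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  term_map <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      ps_abort(sprintf("line %d of %s: gene set needs id, description and >= 1 member",
                       i, path), "parse_error", line = i)
    }
    id <- fields[1]
    if (id %in% names(term_map)) {
      ps_abort(sprintf("duplicate term id '%s' at line %d of %s", id, i, path),
               "duplicate_term_error")
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      ps_abort(sprintf("line %d of %s: empty member list", i, path),
               "parse_error", line = i)
    }
    term_map[[id]] <- list(name = fields[2], genes = members)
  }
  term_map
}

#' Write gene sets to a GMT file
#'
#' @param term_map Named list as returned by [read_gene_sets()].
#' @param path Output path.
#' @export
write_gene_sets <- function(term_map, path) {
  lines <- vapply(names(term_map), function(id) {
    paste(c(id, term_map[[id]]$name, term_map[[id]]$genes), collapse = "\t")
  }, character(1))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) ps_abort(sprintf("cannot write to %s", path), "io_error")
  invisible(path)
}

#' Read or write a binary gene-flag table
#'
#' One row per gene, one 0/1 column per flag label (the format mirrors
#' binary gene-set memberships such as human-ortholog / disease-associated /
#' kinase status).
#'
#' @param path TSV path.
#' @return data.frame with column `gene` and integer 0/1 flag columns.
#' @export
read_gene_flags <- function(path) {
  if (!file.exists(path)) {
    ps_abort(sprintf("flags file not found: %s", path), "io_error")
  }
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"gene" %in% names(df)) {
    ps_abort(sprintf("flags file %s lacks a 'gene' column", path),
             "parse_error")
  }
  for (lb in setdiff(names(df), "gene")) {
    if (!all(df[[lb]] %in% c(0L, 1L))) {
      ps_abort(sprintf("flag column '%s' in %s is not 0/1", lb, path),
               "parse_error")
    }
  }
  df
}

#' @rdname read_gene_flags
#' @param flags data.frame as returned by [read_gene_flags()].
#' @export
write_gene_flags <- function(flags, path) {
  write_tsv_file(flags, path)
}
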