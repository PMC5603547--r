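## Shared readers/writers. Interchange format is TSV with '#'-prefixed
## provenance header lines; networks are additionally exported as SIF and
## GraphML for Cytoscape.

provenance_header <- function(seed = NULL, params = NULL) {
  h <- c(sprintf("# lncnet %s",
                 as.character(utils::packageVersion("lncnet"))))
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %s", seed))
  if (!is.null(params)) {
    kv <- vapply(names(params), function(k) {
      sprintf("%s=%s", k, paste(format(params[[k]]), collapse = ","))
    }, character(1))
    h <- c(h, paste("#", paste(kv, collapse = " ")))
  }
  h
}

#' Write a table as TSV with a provenance header
#'
#' Writes a data frame as tab-separated values preceded by `#`-prefixed
#' header lines recording the package version and, optionally, the seed and
#' parameters that produced it. Companion reader: [read_tsv()].
#'
#' @param x data frame.
#' @param path output file.
#' @param seed,params optional provenance (seed and named parameter list).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, seed = NULL, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, params), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a provenance-headed TSV
#'
#' @param path file written by [write_tsv()] (or any TSV whose comment
#'   lines start with `#`).
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a count matrix from TSV
#'
#' Expects gene ids in the first column and one column per sample.
#'
#' @param path TSV file (comment lines `#` allowed).
#' @return integer matrix with gene row names and sample column names.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  check_counts(m)
}

#' Write a count matrix to TSV
#'
#' @param counts matrix with dimnames.
#' @param path output file.
#' @param seed,params optional provenance.
#' @export
write_counts <- function(counts, path, seed = NULL, params = NULL) {
  counts <- check_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, seed = seed, params = params)
}

#' Read gene sets in GMT format
#'
#' One pathway per line: id, description, then tab-separated gene ids
#' (parsed with `fgsea::gmtPathways`).
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    stop("reading GMT files requires the 'fgsea' package", call. = FALSE)
  }
  fgsea::gmtPathways(path)
}

#' Write gene sets in GMT format
#'
#' @param pathways named list of character vectors.
#' @param path output file.
#' @param descriptions optional character vector of descriptions (defaults
#'   to the pathway ids).
#' @export
write_gmt <- function(pathways, path, descriptions = names(pathways)) {
  stopifnot(!is.null(names(pathways)), length(descriptions) == length(pathways))
  lines <- vapply(seq_along(pathways), function(i) {
    paste(c(names(pathways)[i], descriptions[i], pathways[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Transcript lengths from a FASTA file
#'
#' @param path FASTA file (read with `Biostrings::readDNAStringSet`).
#' @return named integer vector of sequence lengths.
#' @export
read_transcript_lengths <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA files requires the 'Biostrings' package", call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  ## keep only the id token of the FASTA header
  stats::setNames(Biostrings::width(seqs),
                  vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1))
}

## Edge list of either network class in (source, interaction, target) form.
network_edge_df <- function(network) {
  if (inherits(network, "coexpression_network")) {
    data.frame(source = network$edges$lnc_id, interaction = "coexp",
               target = network$edges$mrna_id, stringsAsFactors = FALSE)
  } else if (inherits(network, "lnc_pathway_network")) {
    data.frame(source = network$edges$lnc_id, interaction = "regulates",
               target = network$edges$pathway_id, stringsAsFactors = FALSE)
  } else stop("not a network object", call. = FALSE)
}

#' Export a network as SIF
#'
#' Simple interaction format (`source<TAB>interaction<TAB>target`), readable
#' by Cytoscape.
#'
#' @param network a `coexpression_network` or `lnc_pathway_network`.
#' @param path output file.
#' @export
export_sif <- function(network, path) {
  df <- network_edge_df(network)
  writeLines(sprintf("%s\t%s\t%s", df$source, df$interaction, df$target), path)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Builds an `igraph` graph (node attributes `biotype`/`type`, edge weight
#' `r` where available) and writes Cytoscape-compatible GraphML.
#'
#' @param network a `coexpression_network` or `lnc_pathway_network`.
#' @param path output file.
#' @export
export_graphml <- function(network, path) {
  if (inherits(network, "coexpression_network")) {
    e <- network$edges[, c("lnc_id", "mrna_id", "r", "qvalue")]
    v <- network$nodes[, c("id", "biotype", "degree")]
  } else if (inherits(network, "lnc_pathway_network")) {
    e <- network$edges[, c("lnc_id", "pathway_id", "n_support")]
    v <- data.frame(id = unique(c(network$edges$lnc_id, network$edges$pathway_id)),
                    stringsAsFactors = FALSE)
    v$type <- ifelse(v$id %in% network$edges$lnc_id, "lncRNA", "pathway")
  } else stop("not a network object", call. = FALSE)
  g <- igraph::graph_from_data_frame(e, directed = FALSE, vertices = v)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
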