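#' Gene registry
#'
#' A gene registry holds the proteome the pipeline operates on: one row per
#' gene with its locus tag, optional UniProt accession, and wild-type
#' consensus amino-acid sequence.  All downstream coordinates (features,
#' mutations, topology spans) are 1-based positions in these sequences.
#'
#' @param gene_id character vector of locus tags (opaque, case-sensitive).
#' @param aa_sequence character vector of amino-acid sequences using the 20
#'   standard one-letter codes plus `X`.
#' @param uniprot_id optional character vector of UniProt accessions.
#' @return A `gene_registry` data frame with columns `gene_id`,
#'   `uniprot_id`, `aa_sequence`, `length`.
#' @export
gene_registry <- function(gene_id, aa_sequence, uniprot_id = NA_character_) {
  gene_id <- as.character(gene_id)
  aa_sequence <- toupper(as.character(aa_sequence))
  if (length(gene_id) != length(aa_sequence))
    stop("gene_id and aa_sequence must have equal length")
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id in registry: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", aa_sequence) | nchar(aa_sequence) == 0
  if (any(bad))
    stop("invalid amino-acid sequence for gene(s): ",
         paste(gene_id[bad], collapse = ", "))
  reg <- data.frame(
    gene_id = gene_id,
    uniprot_id = rep_len(as.character(uniprot_id), length(gene_id)),
    aa_sequence = aa_sequence,
    length = nchar(aa_sequence),
    stringsAsFactors = FALSE
  )
  rownames(reg) <- reg$gene_id
  class(reg) <- c("gene_registry", "data.frame")
  reg
}

#' Read a gene registry from a FASTA file
#'
#' Record identifiers become gene ids; an optional second whitespace-separated
#' token in the header is taken as the UniProt accession.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return A [gene_registry()] data frame.
#' @export
read_gene_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  hdr <- strsplit(names(seqs), "\\s+")
  ids <- vapply(hdr, `[`, character(1), 1L)
  up <- vapply(hdr, function(h) if (length(h) >= 2) h[2] else NA_character_,
               character(1))
  gene_registry(ids, as.character(seqs), up)
}

#' Write a gene registry to FASTA
#'
#' @param registry a [gene_registry()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(registry, path) {
  hdr <- ifelse(is.na(registry$uniprot_id), registry$gene_id,
                paste(registry$gene_id, registry$uniprot_id))
  seqs <- Biostrings::AAStringSet(registry$aa_sequence)
  names(seqs) <- hdr
  Biostrings::writeXStringSet(seqs, path, width = 60)
  invisible(path)
}

#' Construct a complex target
#'
#' A complex target is the gene copy-number multiset a structural
#' representation must recreate: e.g. an annotated hetero-trimer
#' `{gA: 2, gB: 1}`.
#'
#' @param complex_id identifier string.
#' @param stoichiometry named integer vector, gene id to copy count (>= 1).
#' @param provenance one of `"ANNOTATED"`, `"EXPECTED_MONOMER"`,
#'   `"REANNOTATED"`.
#' @return A `complex_target` object.
#' @export
complex_target <- function(complex_id, stoichiometry,
                           provenance = c("ANNOTATED", "EXPECTED_MONOMER",
                                          "REANNOTATED")) {
  provenance <- match.arg(provenance)
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop("stoichiometry must be a named vector (gene_id -> copies)")
  st <- stoichiometry[order(names(stoichiometry))]
  if (any(st != round(st)) || any(st < 1))
    stop("copy counts must be positive integers in complex ", complex_id)
  structure(
    list(complex_id = as.character(complex_id),
         stoichiometry = stats::setNames(as.integer(st), names(st)),
         provenance = provenance),
    class = "complex_target"
  )
}

#' @export
print.complex_target <- function(x, ...) {
  cat("<complex_target> ", x$complex_id, " [", x$provenance, "] ",
      stoich_signature(x$stoichiometry), "\n", sep = "")
  invisible(x)
}

#' Canonical signature string of a gene stoichiometry
#'
#' Genes are sorted so that identical multisets always yield identical
#' strings, e.g. `"gA:2|gB:1"`.
#'
#' @param stoichiometry named integer vector.
#' @return A character scalar.
#' @export
stoich_signature <- function(stoichiometry) {
  st <- stoichiometry[order(names(stoichiometry))]
  paste(sprintf("%s:%d", names(st), as.integer(st)), collapse = "|")
}

#' Parse a signature / stoichiometry string
#'
#' Inverse of [stoich_signature()]; also accepts comma-separated pairs as
#' used in the targets table.
#'
#' @param x string like `"gA:2|gB:1"` or `"gA:2,gB:1"`.
#' @return Named integer vector.
#' @export
parse_stoichiometry <- function(x) {
  parts <- strsplit(trimws(x), "[|,]")[[1]]
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, ":")
  if (any(lengths(kv) != 2))
    stop("malformed stoichiometry string: ", x)
  genes <- trimws(vapply(kv, `[`, character(1), 1L))
  copies <- suppressWarnings(as.numeric(vapply(kv, `[`, character(1), 2L)))
  if (any(is.na(copies)) || any(copies != round(copies)) || any(copies <= 0))
    stop("copy counts must be positive integers in: ", x)
  if (anyDuplicated(genes))
    stop("duplicate gene in stoichiometry string: ", x)
  stats::setNames(as.integer(copies), genes)[order(genes)]
}

#' Load complex targets from a delimited table
#'
#' Tab-separated with columns `complex_id` and `stoichiometry`
#' (comma-separated `gene:copies` pairs).  Rows referencing genes absent from
#' the registry are skipped with a warning; non-positive or non-integer copy
#' counts are validation errors naming the row.
#'
#' @param path TSV file (or a data frame with the same columns).
#' @param registry a [gene_registry()].
#' @return List of [complex_target()]s with an attribute `skipped` holding
#'   the skipped rows (complex id and missing genes).
#' @export
load_complex_targets <- function(path, registry) {
  tab <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("complex_id", "stoichiometry") %in% names(tab)))
    stop("targets table needs columns complex_id, stoichiometry")
  if (anyDuplicated(tab$complex_id))
    stop("duplicate complex_id rows: ",
         paste(unique(tab$complex_id[duplicated(tab$complex_id)]),
               collapse = ", "))
  out <- list()
  skipped <- data.frame(complex_id = character(), missing_genes = character(),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    cid <- tab$complex_id[i]
    st <- tryCatch(parse_stoichiometry(tab$stoichiometry[i]), error = function(e)
      stop("row ", i, " (", cid, "): ", conditionMessage(e), call. = FALSE))
    missing <- setdiff(names(st), registry$gene_id)
    if (length(missing)) {
      skipped <- rbind(skipped, data.frame(
        complex_id = cid, missing_genes = paste(missing, collapse = ","),
        stringsAsFactors = FALSE))
      next
    }
    out[[cid]] <- complex_target(cid, st, "ANNOTATED")
  }
  if (nrow(skipped))
    warning(nrow(skipped), " target row(s) referenced unknown genes and were skipped")
  attr(out, "skipped") <- skipped
  out
}

#' Add expected-monomer targets for unannotated genes
#'
#' Every registered gene that appears in no annotated complex is assumed to
#' act as a monomer and receives a `{gene: 1}` target with provenance
#' `EXPECTED_MONOMER`, so the target set covers the whole proteome.
#'
#' @param registry a [gene_registry()].
#' @param annotated list of [complex_target()]s.
#' @return The annotated list extended with one monomer target per uncovered
#'   gene (named `MONOMER_<gene>`).
#' @export
infer_monomer_targets <- function(registry, annotated) {
  covered <- unique(unlist(lapply(annotated, function(t) names(t$stoichiometry))))
  uncovered <- setdiff(registry$gene_id, covered)
  extra <- lapply(uncovered, function(g)
    complex_target(paste0("MONOMER_", g), stats::setNames(1L, g),
                   "EXPECTED_MONOMER"))
  names(extra) <- vapply(extra, `[[`, character(1), "complex_id")
  c(annotated, extra)
}

#' Serialize complex targets to a TSV table
#'
#' @param targets list of [complex_target()]s.
#' @param path optional output file; when `NULL` the data frame is returned
#'   without writing.
#' @return Data frame with columns `complex_id`, `stoichiometry`,
#'   `provenance`.
#' @export
write_complex_targets <- function(targets, path = NULL) {
  df <- data.frame(
    complex_id = vapply(targets, `[[`, character(1), "complex_id"),
    stoichiometry = vapply(targets, function(t)
      paste(sprintf("%s:%d", names(t$stoichiometry), t$stoichiometry),
            collapse = ","), character(1)),
    provenance = vapply(targets, `[[`, character(1), "provenance"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

#' Total amino-acid size of a complex target
#'
#' Sum over genes of copy count times gene length.
#'
#' @param target a [complex_target()].
#' @param registry a [gene_registry()].
#' @return Integer AA count.
#' @export
target_total_aa <- function(target, registry) {
  st <- target$stoichiometry
  lens <- registry[names(st), "length"]
  if (anyNA(lens))
    stop("target ", target$complex_id, " references unknown gene(s)")
  sum(as.numeric(st) * lens)
}
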