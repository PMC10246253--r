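#' Enumerate pseudo-structures for a structure record
#'
#' A pseudo-structure is a hypothetical assignment of exactly one gene to
#' each entity of a structure file, recreating the file's chain
#' stoichiometry: entity 1 with chains A, B and C assigned gene g always
#' yields the homotrimer `{g: 3}`.  Because sequence searches can map a
#' single entity to several genes, all combinations are materialized by a
#' depth-first tree search over the per-entity candidate lists; the output
#' order is deterministic (entities sorted by id, candidate genes sorted).
#'
#' When the Cartesian product would exceed `max_combinations`, each entity's
#' candidate list is pruned to its `top_k` highest-identity genes before
#' enumeration, keeping worst cases bounded and deterministic.
#'
#' @param record a `structure_record`.
#' @param candidates named list, entity id -> list of
#'   `chain_gene_alignment`s for that entity.  Entities with no candidates
#'   yield no pseudo-structures.
#' @param registry a [gene_registry()] (used for scoring weights).
#' @param max_combinations combinatorial guard (default 10000).
#' @param top_k per-entity candidate cap applied when the guard trips.
#' @return List of `pseudo_structure` objects, scored.
#' @export
enumerate_pseudo_structures <- function(record, candidates, registry,
                                        max_combinations = 10000L,
                                        top_k = 5L) {
  ents <- sort(names(record$entities))
  cand <- lapply(ents, function(e) {
    cl <- candidates[[e]]
    if (is.null(cl)) return(list())
    cl[order(vapply(cl, `[[`, character(1), "gene_id"))]
  })
  names(cand) <- ents
  if (any(lengths(cand) == 0)) return(list())
  if (prod(lengths(cand)) > max_combinations) {
    cand <- lapply(cand, function(cl) {
      ident <- vapply(cl, `[[`, numeric(1), "identity")
      # stable: ties keep gene-id order
      cl[order(-ident)][seq_len(min(top_k, length(cl)))]
    })
    cand <- lapply(cand, function(cl)
      cl[order(vapply(cl, `[[`, character(1), "gene_id"))])
  }
  out <- list()
  n <- length(ents)
  pick <- vector("list", n)
  recurse <- function(i) {
    if (i > n) {
      out[[length(out) + 1L]] <<- build_pseudo_structure(record, pick, registry)
      return(invisible())
    }
    for (al in cand[[i]]) {
      pick[[i]] <<- al
      recurse(i + 1L)
    }
  }
  recurse(1L)
  out
}

build_pseudo_structure <- function(record, alignments, registry) {
  ents <- sort(names(record$entities))
  genes <- vapply(alignments, `[[`, character(1), "gene_id")
  idents <- vapply(alignments, `[[`, numeric(1), "identity")
  names(genes) <- ents
  names(idents) <- ents
  copies <- vapply(record$entities[ents], `[[`, integer(1), "copy_count")
  st <- tapply(copies, genes, sum)
  st <- stats::setNames(as.integer(st), names(st))[order(names(st))]
  ps <- structure(
    list(structure_id = record$structure_id, source = record$source,
         assignment = genes, per_entity_identity = idents,
         gene_stoichiometry = st,
         signature = stoich_signature(st),
         alignments = stats::setNames(alignments, ents),
         quality = NA_real_),
    class = "pseudo_structure")
  ps$quality <- score_pseudo_structure(ps, registry, record)
  ps$ps_id <- paste0(record$structure_id, "/",
                     paste(genes, collapse = "+"))
  ps
}

#' Score a pseudo-structure
#'
#' The quality is the identity of each entity-gene mapping averaged with
#' weights equal to the fraction of the complex's amino acids that entity
#' represents: `sum(copies * gene_length * identity) /
#' sum(copies * gene_length)`.
#'
#' @param ps a `pseudo_structure` with `per_entity_identity` populated.
#' @param registry a [gene_registry()].
#' @param record the originating `structure_record` (for entity copy
#'   counts); when omitted, copy counts stored on the pseudo-structure are
#'   used.
#' @return Quality in `[0, 1]`.
#' @export
score_pseudo_structure <- function(ps, registry, record = NULL) {
  ents <- names(ps$assignment)
  copies <- if (!is.null(record))
    vapply(record$entities[ents], `[[`, integer(1), "copy_count")
  else ps$entity_copies[ents]
  lens <- registry[ps$assignment, "length"]
  if (anyNA(lens))
    stop("pseudo-structure references unknown gene(s): ",
         paste(setdiff(ps$assignment, registry$gene_id), collapse = ", "))
  w <- as.numeric(copies) * lens
  if (sum(w) <= 0) stop("zero total amino-acid weight")
  sum(w * ps$per_entity_identity[ents]) / sum(w)
}

#' @export
print.pseudo_structure <- function(x, ...) {
  cat("<pseudo_structure> ", x$ps_id, " [", x$source, "] ", x$signature,
      sprintf(" quality=%.3f", x$quality), "\n", sep = "")
  invisible(x)
}

#' Keep the best pseudo-structure per structure-gene stoichiometry
#'
#' Pseudo-structures of the same structure file that imply the same gene
#' stoichiometry are redundant; only the highest-quality one is kept.
#' Quality ties are broken lexicographically (structure id, then the
#' assignment string) for reproducibility.  Distinct signatures, and
#' identical signatures from different structure files, are all kept -- the
#' complex matcher sees every file.
#'
#' @param pss list of scored `pseudo_structure`s.
#' @return Deduplicated list, ordered by structure id then signature.
#' @export
dedupe_best <- function(pss) {
  if (length(pss) == 0) return(pss)
  key <- vapply(pss, function(p) paste(p$structure_id, p$signature, sep = "\r"),
                character(1))
  picked <- lapply(split(seq_along(pss), key), function(idx) {
    qs <- vapply(pss[idx], `[[`, numeric(1), "quality")
    best <- idx[qs == max(qs)]
    ids <- vapply(pss[best], `[[`, character(1), "ps_id")
    best[order(ids)][1]
  })
  out <- pss[unlist(picked, use.names = FALSE)]
  ord <- order(vapply(out, `[[`, character(1), "structure_id"),
               vapply(out, `[[`, character(1), "signature"))
  out[ord]
}

#' Export pseudo-structures as a table
#'
#' @param pss list of `pseudo_structure`s.
#' @param path optional TSV output file.
#' @return Data frame (structure_id, source, assignment, signature,
#'   quality).
#' @export
write_pseudo_structures <- function(pss, path = NULL) {
  df <- data.frame(
    ps_id = vapply(pss, `[[`, character(1), "ps_id"),
    structure_id = vapply(pss, `[[`, character(1), "structure_id"),
    source = vapply(pss, `[[`, character(1), "source"),
    assignment = vapply(pss, function(p)
      paste(sprintf("%s=%s", names(p$assignment), p$assignment),
            collapse = ","), character(1)),
    signature = vapply(pss, `[[`, character(1), "signature"),
    quality = vapply(pss, `[[`, numeric(1), "quality"),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
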