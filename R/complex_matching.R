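#' Find all structural matches for a complex target
#'
#' Enumerates every distinct multiset of pseudo-structures whose gene
#' stoichiometries sum *exactly* to the target (no over- or under-coverage:
#' a tetramer part cannot stand in for a dimer target).  A part may be used
#' several times -- rebuilding a homotetramer from one monomeric model takes
#' four copies of it.  The search runs level-by-level on the remaining
#' demand with memoization and a canonical non-decreasing part order, so the
#' result is deterministic and equals exhaustive enumeration.  Targets whose
#' search exceeds `max_states` explored states are abandoned and reported.
#'
#' @param target a [complex_target()].
#' @param pss list of scored, deduplicated `pseudo_structure`s.
#' @param registry a [gene_registry()] (amino-acid weights for match
#'   quality).
#' @param max_states search cap.
#' @return List of `complex_match` objects (possibly empty), with attribute
#'   `aborted = TRUE` when the cap was hit.
#' @export
match_complex <- function(target, pss, registry, max_states = 50000L) {
  tst <- target$stoichiometry
  genes <- names(tst)
  usable <- Filter(function(p) {
    st <- p$gene_stoichiometry
    all(names(st) %in% genes) && all(st <= tst[names(st)])
  }, pss)
  usable <- usable[order(vapply(usable, `[[`, character(1), "ps_id"))]
  n <- length(usable)
  if (n == 0) return(structure(list(), aborted = FALSE))
  part_vec <- lapply(usable, function(p) {
    v <- stats::setNames(integer(length(genes)), genes)
    v[names(p$gene_stoichiometry)] <- p$gene_stoichiometry
    v
  })
  memo <- new.env(parent = emptyenv())
  states <- 0L
  aborted <- FALSE
  solve <- function(rem, i) {
    if (all(rem == 0L)) return(list(integer(0)))
    if (i > n) return(list())
    key <- paste(paste(rem, collapse = ","), i, sep = ";")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    states <<- states + 1L
    if (states > max_states) {
      aborted <<- TRUE
      return(list())
    }
    sols <- list()
    for (j in i:n) {
      pv <- part_vec[[j]]
      if (all(pv <= rem)) {
        for (s in solve(rem - pv, j))
          sols[[length(sols) + 1L]] <- c(j, s)
      }
      if (aborted) break
    }
    memo[[key]] <- sols
    sols
  }
  sols <- solve(tst, 1L)
  if (aborted)
    return(structure(list(), aborted = TRUE))
  matches <- lapply(sols, function(idx)
    build_complex_match(target, usable[idx], registry))
  keys <- vapply(matches, `[[`, character(1), "key")
  structure(matches[order(keys)], aborted = FALSE)
}

build_complex_match <- function(target, parts, registry) {
  covered <- Reduce(function(acc, p) {
    st <- p$gene_stoichiometry
    acc[names(st)] <- acc[names(st)] + st
    acc
  }, parts, stats::setNames(integer(length(target$stoichiometry)),
                            names(target$stoichiometry)))
  w <- vapply(parts, function(p)
    sum(as.numeric(p$gene_stoichiometry) *
          registry[names(p$gene_stoichiometry), "length"]), numeric(1))
  q <- vapply(parts, `[[`, numeric(1), "quality")
  ids <- sort(vapply(parts, `[[`, character(1), "ps_id"))
  structure(
    list(complex_id = target$complex_id,
         part_ids = ids,
         parts = parts[order(vapply(parts, `[[`, character(1), "ps_id"))],
         covered = covered,
         n_parts = length(parts),
         representation = if (length(parts) == 1L) "SINGLE" else "MULTI",
         match_quality = sum(w * q) / sum(w),
         sources = vapply(parts, `[[`, character(1), "source"),
         key = paste(ids, collapse = "&")),
    class = "complex_match")
}

#' @export
print.complex_match <- function(x, ...) {
  cat("<complex_match> ", x$complex_id, " [", x$representation, "] ",
      x$n_parts, " part(s), quality ", sprintf("%.3f", x$match_quality),
      ": ", x$key, "\n", sep = "")
  invisible(x)
}

SOURCE_PRIORITY <- c(PDB = 1, SWISS = 2, AF_MULTIMER = 3, ALPHAFOLD = 4,
                     ITASSER = 5)

#' Select the representative match for a complex
#'
#' Ordered preference policy: (1) a single-structure match whose sole part
#' is an AlphaFold-Multimer model wins outright (such models were already
#' quality-screened at generation time); (2) otherwise a single-structure
#' match with quality above `single_cutoff` (default 0.70) wins, the
#' highest-quality such match if several; (3) otherwise the
#' quality/quaternary-structure trade-off: maximum match quality, ties
#' broken by fewer parts, then by best part-source priority
#' (PDB > SWISS > AF-Multimer > AlphaFold > I-TASSER), then
#' lexicographically.  The policy is a total order: permuting the input
#' never changes the winner.
#'
#' @param matches non-empty list of `complex_match`es.
#' @param single_cutoff identity threshold for the single-structure
#'   preference.
#' @return The selected `complex_match`.
#' @export
select_representative <- function(matches, single_cutoff = 0.70) {
  if (length(matches) == 0) stop("no matches to select from")
  matches <- matches[order(vapply(matches, `[[`, character(1), "key"))]
  is_single <- vapply(matches, function(m) m$n_parts == 1L, logical(1))
  afm <- is_single & vapply(matches, function(m)
    m$sources[1] == "AF_MULTIMER", logical(1))
  pick_best <- function(idx) {
    ms <- matches[idx]
    q <- vapply(ms, `[[`, numeric(1), "match_quality")
    idx[order(-q, vapply(ms, `[[`, character(1), "key"))][1]
  }
  if (any(afm)) return(matches[[pick_best(which(afm))]])
  good_single <- is_single & vapply(matches, function(m)
    m$match_quality > single_cutoff, logical(1))
  if (any(good_single)) return(matches[[pick_best(which(good_single))]])
  q <- vapply(matches, `[[`, numeric(1), "match_quality")
  np <- vapply(matches, `[[`, integer(1), "n_parts")
  src <- vapply(matches, function(m)
    min(SOURCE_PRIORITY[m$sources]), numeric(1))
  key <- vapply(matches, `[[`, character(1), "key")
  matches[[order(-q, np, src, key)[1]]]
}

#' Build de novo prediction requests for unmatched complexes
#'
#' Complexes that no combination of catalog structures can recreate are
#' queued for de novo multimer prediction.  A request is eligible when the
#' complex's total size is below `max_aa` (default 2000 amino acids, the
#' practical fold-prediction bound); larger complexes are emitted with
#' `eligible = FALSE` and need a manual sub-complex split.
#'
#' @param unmatched list of [complex_target()]s with no complete match.
#' @param registry a [gene_registry()].
#' @param dir optional directory; when given, one FASTA per request is
#'   written with one entry per subunit copy (the stoichiometric ratio).
#' @param max_aa eligibility bound in amino acids.
#' @return Data frame (complex_id, total_aa, eligible, fasta).
#' @export
build_de_novo_requests <- function(unmatched, registry, dir = NULL,
                                   max_aa = 2000L) {
  rows <- lapply(unmatched, function(t) {
    total <- target_total_aa(t, registry)
    fasta <- NA_character_
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      st <- t$stoichiometry
      ids <- unlist(lapply(names(st), function(g)
        sprintf("%s_copy%d", g, seq_len(st[[g]]))))
      seqs <- unlist(lapply(names(st), function(g)
        rep(registry[g, "aa_sequence"], st[[g]])))
      ss <- Biostrings::AAStringSet(seqs)
      names(ss) <- ids
      fasta <- file.path(dir, paste0(t$complex_id, ".fasta"))
      Biostrings::writeXStringSet(ss, fasta, width = 60)
    }
    data.frame(complex_id = t$complex_id, total_aa = total,
               eligible = total < max_aa, fasta = fasta,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(complex_id = character(), total_aa = numeric(),
               eligible = logical(), fasta = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
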