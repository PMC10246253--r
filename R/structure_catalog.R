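#' Structure sources
#'
#' Recognized provenance classes for coordinate files.  `PDB` bioassemblies
#' and `SWISS` homology models may be oligomeric; `ITASSER` and `ALPHAFOLD`
#' records are monomeric by construction; `AF_MULTIMER` models are de novo
#' multimer predictions.
#' @export
STRUCTURE_SOURCES <- c("PDB", "SWISS", "ITASSER", "ALPHAFOLD", "AF_MULTIMER")

MONOMERIC_SOURCES <- c("ITASSER", "ALPHAFOLD")

#' Parse a coordinate file into a structure record
#'
#' Reads an mmCIF or PDB file (via bio3d), keeps one CA atom per residue and
#' any cysteine SG atoms, renumbers residues 1-based and sequential per
#' chain, and groups chains into entities.  mmCIF entity identifiers are
#' honoured when present; PDB-format files (which carry no entity records)
#' fall back to grouping chains by exact sequence equality.  For deep-learning
#' models the per-residue confidence stored in the B-factor column is
#' averaged into `model_metrics$mean_confidence`.
#'
#' @param file path to a `.pdb` or `.cif` coordinate file.
#' @param source one of [STRUCTURE_SOURCES].
#' @param structure_id identifier; defaults to the file name without
#'   extension.
#' @param model_metrics optional named numeric vector of model quality
#'   metrics (`GMQE`, `QMN4`, `QSPRD`, ...).
#' @return A `structure_record`: list with `structure_id`, `source`,
#'   `atoms` (CA table: chain, resno, auth_resno, aa, x, y, z, b),
#'   `sg` (cysteine SG coordinates), `entities` (list of
#'   entity_id, chain_ids, sequence, copy_count), `model_metrics`,
#'   `unusable` flag.
#' @export
parse_structure <- function(file, source, structure_id = NULL,
                            model_metrics = NULL) {
  source <- match.arg(source, STRUCTURE_SOURCES)
  if (is.null(structure_id))
    structure_id <- sub("\\.(pdb|cif|ent)$", "", basename(file))
  is_cif <- grepl("\\.cif$", file, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) suppressWarnings(bio3d::read.cif(file)) else
      suppressWarnings(bio3d::read.pdb(file)),
    error = function(e) stop("cannot parse coordinate file ", file, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  ca <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0)
    stop("unusable structure (no CA atoms): ", file)
  # one CA per residue: drop altloc duplicates, keep first
  key <- paste(ca$chain, ca$resno)
  ca <- ca[!duplicated(key), , drop = FALSE]
  ca <- ca[order(ca$chain, seq_len(nrow(ca))), , drop = FALSE]

  chains <- unique(ca$chain)
  atoms <- do.call(rbind, lapply(chains, function(ch) {
    sub <- ca[ca$chain == ch, , drop = FALSE]
    data.frame(chain = ch, resno = seq_len(nrow(sub)), auth_resno = sub$resno,
               aa = bio3d::aa321(sub$resid), x = sub$x, y = sub$y, z = sub$z,
               b = sub$b, stringsAsFactors = FALSE)
  }))
  rownames(atoms) <- NULL

  sg <- at[at$type == "ATOM" & at$elety == "SG", , drop = FALSE]
  sg_df <- if (nrow(sg)) {
    # translate author numbering to internal sequential numbering
    idx <- match(paste(sg$chain, sg$resno), paste(atoms$chain, atoms$auth_resno))
    keep <- !is.na(idx)
    data.frame(chain = sg$chain[keep], resno = atoms$resno[idx[keep]],
               x = sg$x[keep], y = sg$y[keep], z = sg$z[keep],
               stringsAsFactors = FALSE)
  } else {
    data.frame(chain = character(), resno = integer(), x = numeric(),
               y = numeric(), z = numeric(), stringsAsFactors = FALSE)
  }

  seqs <- vapply(chains, function(ch)
    paste(atoms$aa[atoms$chain == ch], collapse = ""), character(1))

  # entity grouping: mmCIF entity id lands in bio3d's segid column
  ent_of_chain <- NULL
  if (is_cif && "segid" %in% names(ca) && !anyNA(ca$segid)) {
    ent_of_chain <- vapply(chains, function(ch)
      as.character(ca$segid[ca$chain == ch][1]), character(1))
    # entities must be sequence-consistent; otherwise fall back
    ok <- !anyNA(ent_of_chain) &&
      all(vapply(split(seqs, ent_of_chain), function(s)
        length(unique(s)) == 1L, logical(1)))
    if (!ok) ent_of_chain <- NULL
  }
  if (is.null(ent_of_chain)) {
    uniq <- unique(seqs)
    ent_of_chain <- stats::setNames(as.character(match(seqs, uniq)), chains)
  }
  entities <- lapply(sort(unique(ent_of_chain)), function(eid) {
    ch <- chains[ent_of_chain == eid]
    list(entity_id = eid, chain_ids = ch, sequence = seqs[[ch[1]]],
         copy_count = length(ch))
  })
  names(entities) <- vapply(entities, `[[`, character(1), "entity_id")

  if (source %in% MONOMERIC_SOURCES &&
      (length(entities) != 1L || entities[[1]]$copy_count != 1L))
    stop(source, " records must be monomeric (one entity, one chain): ", file)

  mm <- as.list(model_metrics)
  if (source %in% c("ALPHAFOLD", "AF_MULTIMER"))
    mm$mean_confidence <- mean(atoms$b)

  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", file)

  structure(
    list(structure_id = structure_id, source = source, atoms = atoms,
         sg = sg_df, entities = entities,
         model_metrics = if (length(mm)) mm else NULL,
         unusable = FALSE, file = file),
    class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat("<structure_record> ", x$structure_id, " [", x$source, "] ",
      length(x$entities), " entit", ifelse(length(x$entities) == 1, "y", "ies"),
      ", ", length(unique(x$atoms$chain)), " chain(s), ",
      nrow(x$atoms), " residues", if (isTRUE(x$unusable)) " (UNUSABLE)" else "",
      "\n", sep = "")
  invisible(x)
}

#' CA coordinates of a structure record as a matrix
#'
#' @param record a `structure_record`.
#' @param chain optional chain id filter.
#' @return Numeric matrix with one row per residue (columns x, y, z), row
#'   names `chain:resno`.
#' @export
ca_coords <- function(record, chain = NULL) {
  a <- record$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- paste(a$chain, a$resno, sep = ":")
  m
}

#' Align a gene sequence to a structure entity
#'
#' Global (Needleman-Wunsch, BLOSUM62) pairwise alignment of the entity's
#' chain sequence to the gene sequence.  Identity is the number of identical
#' aligned positions divided by the *gene* length, so it doubles as a
#' structural-coverage measure: a perfect model of half the gene scores 0.5.
#' The residue map sends chain residue numbers to gene positions for every
#' aligned (identical or substituted) column and is therefore injective and
#' strictly increasing.
#'
#' @param gene single-row subset of a [gene_registry()] (or a list with
#'   `gene_id` and `aa_sequence`).
#' @param entity one element of `record$entities`.
#' @param structure_id id recorded in the result.
#' @param min_identity alignments below this identity are kept but flagged.
#' @return A `chain_gene_alignment`: list with `structure_id`, `entity_id`,
#'   `gene_id`, `identity`, `residue_map` (named integer, chain resno ->
#'   gene position), `low_identity` flag.
#' @export
align_gene_to_chain <- function(gene, entity, structure_id = NA_character_,
                                min_identity = 0.2) {
  gseq <- if (is.data.frame(gene)) gene$aa_sequence[1] else gene$aa_sequence
  gid <- if (is.data.frame(gene)) gene$gene_id[1] else gene$gene_id
  cseq <- entity$sequence
  if (!nzchar(gseq) || !nzchar(cseq))
    stop("cannot align empty sequence (gene ", gid, ")")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(cseq), Biostrings::AAString(gseq),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  p <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  ppos <- Biostrings::start(Biostrings::pattern(al)) - 1L
  spos <- Biostrings::start(Biostrings::subject(al)) - 1L
  map_chain <- integer(0); map_gene <- integer(0); n_ident <- 0L
  for (k in seq_along(p)) {
    pc <- p[k]; sc <- s[k]
    if (pc != "-") ppos <- ppos + 1L
    if (sc != "-") spos <- spos + 1L
    if (pc != "-" && sc != "-") {
      map_chain <- c(map_chain, ppos)
      map_gene <- c(map_gene, spos)
      if (pc == sc) n_ident <- n_ident + 1L
    }
  }
  identity <- n_ident / nchar(gseq)
  structure(
    list(structure_id = structure_id, entity_id = entity$entity_id,
         gene_id = gid, identity = identity,
         residue_map = stats::setNames(map_gene, map_chain),
         low_identity = identity < min_identity),
    class = "chain_gene_alignment")
}

#' Invert an alignment's residue map
#'
#' @param alignment a `chain_gene_alignment`.
#' @return Named integer vector, gene position -> chain residue number.
#' @export
invert_residue_map <- function(alignment) {
  rm <- alignment$residue_map
  stats::setNames(as.integer(names(rm)), rm)
}

# string-like flag per residue: fewer than `min_contacts` CA neighbours
# within `radius` among residues at least `seq_sep` apart in sequence
string_like_residues <- function(xyz, min_contacts = 3L, radius = 8,
                                 seq_sep = 3L) {
  n <- nrow(xyz)
  if (n == 0) return(logical(0))
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(seq_len(n), seq_len(n), "-")) >= seq_sep
  counts <- rowSums(d <= radius & sep)
  counts < min_contacts
}

#' Trim string-like unfolded regions from a threading model
#'
#' Iteratively removes maximal runs (length >= `min_run`) of "string-like"
#' residues -- residues whose CA has fewer than 3 CA contacts within 8
#' angstroms among residues at least 3 apart in sequence -- until a fixed
#' point is reached.  Threading models often carry long extended tails and
#' linkers that inflate apparent coverage; trimming them makes the
#' identity-as-coverage metric honest.  If everything is removed the record
#' is flagged unusable.
#'
#' @param record a monomeric `structure_record` with `source == "ITASSER"`.
#' @param min_contacts,radius,seq_sep,min_run criterion parameters.
#' @return The trimmed `structure_record` (residues renumbered
#'   sequentially); `$trimmed_n` counts removed residues.
#' @export
trim_itasser <- function(record, min_contacts = 3L, radius = 8,
                         seq_sep = 3L, min_run = 10L) {
  stopifnot(inherits(record, "structure_record"))
  if (record$source != "ITASSER")
    stop("trim_itasser applies to ITASSER records only")
  atoms <- record$atoms
  removed <- 0L
  repeat {
    if (nrow(atoms) == 0) break
    sl <- string_like_residues(as.matrix(atoms[, c("x", "y", "z")]),
                               min_contacts, radius, seq_sep)
    r <- rle(sl)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    drop <- unlist(mapply(function(v, s, e, l)
      if (v && l >= min_run) s:e else integer(0),
      r$values, starts, ends, r$lengths, SIMPLIFY = FALSE))
    if (length(drop) == 0) break
    atoms <- atoms[-drop, , drop = FALSE]
    removed <- removed + length(drop)
  }
  out <- record
  out$trimmed_n <- removed
  if (nrow(atoms) == 0) {
    out$atoms <- atoms
    out$unusable <- TRUE
    return(out)
  }
  atoms$resno <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  out$atoms <- atoms
  ch <- atoms$chain[1]
  out$entities[[1]]$sequence <- paste(atoms$aa, collapse = "")
  # keep SG atoms of surviving residues, renumbered
  if (nrow(record$sg)) {
    keep_auth <- atoms$auth_resno
    sgk <- record$sg  # sg resno is internal; rebuild from auth mapping
    old <- record$atoms
    sg_auth <- old$auth_resno[match(paste(sgk$chain, sgk$resno),
                                    paste(old$chain, old$resno))]
    sel <- sg_auth %in% keep_auth
    sgk <- sgk[sel, , drop = FALSE]
    sgk$resno <- atoms$resno[match(sg_auth[sel], atoms$auth_resno)]
    out$sg <- sgk
  }
  out
}

#' Quality-control gate for predicted models
#'
#' SWISS-MODEL records fail when any of `GMQE < 0.5`, `QMN4 < -4`,
#' `QSPRD < 0.5`, or gene identity `< 0.7`; a missing metric fails
#' (fail-safe: unknown quality must not silently pass).  Records from other
#' sources pass this gate -- experimental structures are trusted and
#' deep-learning models are screened elsewhere.
#'
#' @param record a `structure_record`.
#' @param alignment the `chain_gene_alignment` supplying the identity.
#' @return List with `pass` (logical) and `reasons` (character).
#' @export
qc_model <- function(record, alignment = NULL) {
  if (record$source != "SWISS")
    return(list(pass = TRUE, reasons = character(0)))
  mm <- record$model_metrics
  reasons <- character(0)
  need <- c(GMQE = 0.5, QSPRD = 0.5)
  for (m in names(need)) {
    v <- mm[[m]]
    if (is.null(v) || is.na(v)) reasons <- c(reasons, paste0(m, " missing"))
    else if (v < need[[m]]) reasons <- c(reasons, paste0(m, " < ", need[[m]]))
  }
  v <- mm[["QMN4"]]
  if (is.null(v) || is.na(v)) reasons <- c(reasons, "QMN4 missing")
  else if (v < -4) reasons <- c(reasons, "QMN4 < -4")
  if (is.null(alignment)) {
    reasons <- c(reasons, "identity missing")
  } else if (alignment$identity < 0.7) {
    reasons <- c(reasons, "identity < 0.7")
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Read a model-metric sidecar table
#'
#' TSV with columns `structure_id`, `metric`, `value`.
#'
#' @param path TSV file.
#' @return Named list: structure_id -> named numeric vector of metrics.
#' @export
read_model_metrics <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("structure_id", "metric", "value") %in% names(tab)))
  lapply(split(tab, tab$structure_id), function(s)
    stats::setNames(as.numeric(s$value), s$metric))
}
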