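#' Parse sequence features from UniProt-style flat-file text
#'
#' Reads `FT` feature lines (modern UniProt layout: feature key plus a
#' `start..end` range or a single position, followed by indented
#' `/note="..."` qualifiers).  Gene blocks are delimited by `ID` lines whose
#' second token is taken as the gene id; a single-gene file without `ID`
#' lines may pass `gene_id` explicitly.  Spans are 1-based inclusive.
#'
#' @param path file path, or a character vector of lines.
#' @param gene_id fallback gene id when the text has no `ID` lines.
#' @return Data frame with columns `gene_id`, `kind`, `start`, `end`,
#'   `note`.
#' @export
parse_uniprot_features <- function(path, gene_id = NA_character_) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  cur <- gene_id
  rows <- list()
  last <- NULL
  for (ln in seq_along(lines)) {
    l <- lines[[ln]]
    if (grepl("^ID\\s+", l)) {
      cur <- strsplit(l, "\\s+")[[1]][2]
      last <- NULL
    } else if (grepl("^FT\\s+[A-Z]", l)) {
      toks <- strsplit(sub("^FT\\s+", "", l), "\\s+")[[1]]
      kind <- toks[1]
      rng <- if (length(toks) >= 2) toks[2] else ""
      m <- regmatches(rng, regexec("^<?(\\d+)(?:\\.\\.>?(\\d+))?$", rng))[[1]]
      if (length(m) == 0 || !nzchar(m[2]))
        stop("malformed feature range at line ", ln, ": ", l)
      start <- as.integer(m[2])
      end <- if (nzchar(m[3])) as.integer(m[3]) else start
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = cur, kind = kind, start = start, end = end,
        note = NA_character_, stringsAsFactors = FALSE)
      last <- length(rows)
    } else if (grepl("^FT\\s+/note=", l) && !is.null(last)) {
      note <- sub("^FT\\s+/note=\"?", "", l)
      note <- sub("\"?\\s*$", "", note)
      rows[[last]]$note <- note
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), kind = character(), start = integer(),
               end = integer(), note = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Parse DeepTMHMM-style 3-line topology predictions
#'
#' Each record is a header line (`>gene_id | TM`), the amino-acid sequence,
#' and a per-residue topology string over the alphabet `I` (inside), `O`
#' (outside), `M` (membrane), `S`/`B` (signal / beta; treated as soluble).
#'
#' @param path file path or character vector of lines.
#' @return Named character vector: gene id -> topology string.
#' @export
parse_deeptmhmm <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no records in topology file")
  topo <- character(0)
  for (h in hdr) {
    if (h + 2 > length(lines))
      stop("truncated 3-line record at line ", h)
    gid <- sub("^>\\s*", "", lines[h])
    gid <- trimws(strsplit(gid, "\\|")[[1]][1])
    tp <- toupper(trimws(lines[h + 2]))
    if (grepl("[^IOMSB]", tp))
      stop("malformed topology string at line ", h + 2)
    topo[gid] <- tp
  }
  topo
}

#' Regions of a per-residue topology string
#'
#' @param topology string over `I`/`O`/`M`/`S`/`B`.
#' @return Data frame (type, start, end), in sequence order.
#' @export
topology_regions <- function(topology) {
  chars <- strsplit(topology, "")[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  data.frame(type = r$values, start = ends - r$lengths + 1L, end = ends,
             stringsAsFactors = FALSE)
}

#' Parse OPM-style output
#'
#' OPM writes the oriented structure with planar layers of dummy membrane
#' atoms (residue name `DUM`) marking the two leaflets; the membrane normal
#' is the z axis.  When dummy atoms are absent (large complexes), a
#' transmembrane-segment table (`chain`, `start`, `end`, chain residue
#' numbering) can be supplied as fallback.
#'
#' @param file OPM coordinate file (PDB format).
#' @param segments optional fallback data frame or TSV path.
#' @return List with `dummy` (list of two point matrices, split by z sign;
#'   `NULL` if no dummy atoms) and `segments` (data frame or `NULL`).
#' @export
parse_opm <- function(file = NULL, segments = NULL) {
  dummy <- NULL
  if (!is.null(file)) {
    pdb <- suppressWarnings(bio3d::read.pdb(file))
    at <- pdb$atom
    dum <- at[at$resid == "DUM", , drop = FALSE]
    if (nrow(dum)) {
      pts <- as.matrix(dum[, c("x", "y", "z")])
      upper <- pts[pts[, 3] > 0, , drop = FALSE]
      lower <- pts[pts[, 3] <= 0, , drop = FALSE]
      if (nrow(upper) >= 3 && nrow(lower) >= 3)
        dummy <- list(L1 = upper, L2 = lower)
    }
  }
  if (is.character(segments))
    segments <- utils::read.delim(segments, stringsAsFactors = FALSE)
  list(dummy = dummy, segments = segments)
}

normalize_topo_label <- function(x) {
  x <- tolower(x)
  out <- rep(NA_character_, length(x))
  out[grepl("cyto", x)] <- "cytoplasmic"
  out[grepl("periplas", x)] <- "periplasmic"
  out[grepl("extracell", x)] <- "extracellular"
  out
}

# map gene positions to (chain, resno) rows over every chain copy
map_gene_positions <- function(record, alignments, gene_id, positions) {
  rows <- list()
  for (e in record$entities) {
    al <- alignments[[e$entity_id]]
    if (is.null(al) || al$gene_id != gene_id) next
    inv <- invert_residue_map(al)
    hit <- inv[as.character(positions)]
    keep <- !is.na(hit)
    if (!any(keep)) next
    for (ch in e$chain_ids)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, resno = as.integer(hit[keep]),
        gene_pos = positions[keep], stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(), resno = integer(), gene_pos = integer(),
               stringsAsFactors = FALSE)
}

empty_res_df <- function()
  data.frame(chain = character(), resno = integer(), stringsAsFactors = FALSE)

#' Build membrane-crossing residue sets from the three topology sources
#'
#' Membrane-crossing residues sit at the leaflet surfaces (transmembrane
#' span termini); membrane-embedded residues sit between them.  Per-gene
#' topology (UniProt, DeepTMHMM) is mapped to every subunit chain of the
#' structure through the gene-chain alignments, so a homotrimer contributes
#' three copies of each crossing residue.
#'
#' \describe{
#'   \item{UNIPROT}{`TRANSMEM` spans: interior residues are embedded, the
#'     two termini are crossing residues labeled by the nearest `TOPO_DOM`
#'     annotation (or alternated when no topological domains exist).}
#'   \item{DEEPTMHMM}{`M` runs are embedded (interior) with termini
#'     crossing; soluble runs alternate between leaflet labels `L1`/`L2`
#'     and each terminus inherits the label of its nearest soluble run.}
#'   \item{OPM}{dummy membrane atoms split by the sign of their
#'     z-coordinate give two coplanar leaflet point sets used directly for
#'     plane fitting; the fallback segment table splits segment termini by
#'     the sign of the CA z-coordinate.}
#' }
#'
#' @param record a `structure_record`.
#' @param alignments named list, entity id -> `chain_gene_alignment` (the
#'   representative assignment).
#' @param uniprot_features features data frame from
#'   [parse_uniprot_features()].
#' @param tmhmm named topology vector from [parse_deeptmhmm()].
#' @param opm result of [parse_opm()].
#' @return List of `membrane_crossing_set` objects (at most one per
#'   source), each with `source`, `embedded`, `groups` (two data frames of
#'   chain/resno with a `label` attribute), `opm_points`.
#' @export
build_crossing_sets <- function(record, alignments, uniprot_features = NULL,
                                tmhmm = NULL, opm = NULL) {
  sets <- list()
  genes <- unique(vapply(alignments, `[[`, character(1), "gene_id"))

  if (!is.null(uniprot_features) && nrow(uniprot_features)) {
    emb <- empty_res_df()
    cross <- data.frame(chain = character(), resno = integer(),
                        label = character(), stringsAsFactors = FALSE)
    for (g in genes) {
      ft <- uniprot_features[uniprot_features$gene_id == g, , drop = FALSE]
      tm <- ft[ft$kind == "TRANSMEM", , drop = FALSE]
      if (!nrow(tm)) next
      tm <- tm[order(tm$start), , drop = FALSE]
      topo <- ft[ft$kind == "TOPO_DOM", , drop = FALSE]
      topo$label <- normalize_topo_label(topo$note)
      topo <- topo[!is.na(topo$label), , drop = FALSE]
      # without topological domains, consecutive span termini alternate
      # sides: span i runs from side (i odd ? L1 : L2) to the opposite side
      term_label <- function(pos, span_i, is_start) {
        if (nrow(topo)) {
          d <- pmax(topo$start - pos, pos - topo$end, 0)
          topo$label[which.min(d)]
        } else {
          first <- c("L1", "L2")[(span_i - 1L) %% 2L + 1L]
          if (is_start) first else setdiff(c("L1", "L2"), first)
        }
      }
      for (i in seq_len(nrow(tm))) {
        s <- tm$start[i]; e <- tm$end[i]
        if (e - s >= 2)
          emb <- rbind(emb, map_gene_positions(record, alignments, g,
                                               (s + 1L):(e - 1L))[, 1:2])
        for (pos in c(s, e)) {
          mp <- map_gene_positions(record, alignments, g, pos)
          if (nrow(mp))
            cross <- rbind(cross, data.frame(
              chain = mp$chain, resno = mp$resno,
              label = term_label(pos, i, pos == s),
              stringsAsFactors = FALSE))
        }
      }
    }
    if (nrow(cross))
      sets[["UNIPROT"]] <- crossing_set_from_labels("UNIPROT", emb, cross)
  }

  if (!is.null(tmhmm)) {
    emb <- empty_res_df()
    cross <- data.frame(chain = character(), resno = integer(),
                        label = character(), stringsAsFactors = FALSE)
    for (g in intersect(genes, names(tmhmm))) {
      reg <- topology_regions(tmhmm[[g]])
      mreg <- reg[reg$type == "M", , drop = FALSE]
      if (!nrow(mreg)) next
      sol <- reg[reg$type != "M", , drop = FALSE]
      sol$label <- c("L1", "L2")[(seq_len(nrow(sol)) - 1L) %% 2L + 1L]
      near_sol <- function(pos) {
        d <- pmax(sol$start - pos, pos - sol$end, 0)
        sol$label[which.min(d)]
      }
      for (i in seq_len(nrow(mreg))) {
        s <- mreg$start[i]; e <- mreg$end[i]
        if (e - s >= 2)
          emb <- rbind(emb, map_gene_positions(record, alignments, g,
                                               (s + 1L):(e - 1L))[, 1:2])
        for (pos in c(s, e)) {
          mp <- map_gene_positions(record, alignments, g, pos)
          if (nrow(mp))
            cross <- rbind(cross, data.frame(chain = mp$chain,
                                             resno = mp$resno,
                                             label = near_sol(pos),
                                             stringsAsFactors = FALSE))
        }
      }
    }
    if (nrow(cross))
      sets[["DEEPTMHMM"]] <- crossing_set_from_labels("DEEPTMHMM", emb, cross)
  }

  if (!is.null(opm) && (!is.null(opm$dummy) ||
                        (!is.null(opm$segments) && nrow(opm$segments)))) {
    if (!is.null(opm$dummy)) {
      zs <- c(mean(opm$dummy$L1[, 3]), mean(opm$dummy$L2[, 3]))
      a <- record$atoms
      inside <- a$z > min(zs) & a$z < max(zs)
      emb <- a[inside, c("chain", "resno"), drop = FALSE]
      rownames(emb) <- NULL
      sets[["OPM"]] <- structure(
        list(source = "OPM", embedded = emb,
             groups = NULL, opm_points = opm$dummy),
        class = "membrane_crossing_set")
    } else {
      seg <- opm$segments
      a <- record$atoms
      emb <- empty_res_df()
      cross <- data.frame(chain = character(), resno = integer(),
                          label = character(), stringsAsFactors = FALSE)
      for (i in seq_len(nrow(seg))) {
        ch <- seg$chain[i]; s <- seg$start[i]; e <- seg$end[i]
        if (e - s >= 2)
          emb <- rbind(emb, data.frame(chain = ch, resno = (s + 1L):(e - 1L),
                                       stringsAsFactors = FALSE))
        for (pos in c(s, e)) {
          z <- a$z[a$chain == ch & a$resno == pos]
          if (length(z) == 1)
            cross <- rbind(cross, data.frame(
              chain = ch, resno = pos,
              label = if (z > 0) "L1" else "L2", stringsAsFactors = FALSE))
        }
      }
      if (nrow(cross))
        sets[["OPM"]] <- crossing_set_from_labels("OPM", emb, cross)
    }
  }
  sets
}

crossing_set_from_labels <- function(source, embedded, cross) {
  labs <- names(sort(table(cross$label), decreasing = TRUE))
  if (length(labs) > 2) labs <- labs[1:2]
  if (length(labs) < 2)
    labs <- c(labs, setdiff(c("L1", "L2"), labs))[1:2]
  labs <- sort(labs)
  g1 <- cross[cross$label == labs[1], c("chain", "resno"), drop = FALSE]
  g2 <- cross[cross$label == labs[2], c("chain", "resno"), drop = FALSE]
  g1 <- unique(g1); g2 <- unique(g2)
  rownames(g1) <- rownames(g2) <- NULL
  attr(g1, "label") <- labs[1]
  attr(g2, "label") <- labs[2]
  embedded <- unique(embedded)
  rownames(embedded) <- NULL
  structure(list(source = source, embedded = embedded,
                 groups = list(g1, g2), opm_points = NULL),
            class = "membrane_crossing_set")
}
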