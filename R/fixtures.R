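#' Synthetic CA backbones
#'
#' Idealized alpha-carbon traces for fixture structures: a compact
#' serpentine globule on a 3.8-angstrom cubic lattice, a straight extended
#' segment at canonical CA spacing, a transmembrane helix (1.5 angstrom
#' rise per residue), and the eight corners of a cube (analytic hull
#' volume).  These are geometric stand-ins, not physical protein models;
#' they are sufficient for every CA-based algorithm in the package.
#'
#' @param n number of residues.
#' @param spacing lattice / chain spacing in angstroms.
#' @param origin 3-vector offset.
#' @name synthetic_backbones
NULL

#' @rdname synthetic_backbones
#' @export
synth_globule <- function(n, spacing = 3.8, origin = c(0, 0, 0)) {
  m <- ceiling(n^(1 / 3))
  coords <- matrix(0, n, 3)
  k <- 0L
  for (z in 0:(m - 1)) for (yy in 0:(m - 1)) for (xx in 0:(m - 1)) {
    if (k >= n) break
    k <- k + 1L
    # boustrophedon ordering keeps consecutive residues adjacent
    x <- if (yy %% 2 == 0) xx else m - 1 - xx
    y <- if (z %% 2 == 0) yy else m - 1 - yy
    coords[k, ] <- c(x, y, z) * spacing
  }
  sweep(coords, 2, origin, "+")
}

#' @rdname synthetic_backbones
#' @param dir unit direction of the segment.
#' @export
synth_line <- function(n, spacing = 3.8, origin = c(0, 0, 0),
                       dir = c(1, 0, 0)) {
  dir <- dir / sqrt(sum(dir^2))
  t(vapply(seq_len(n) - 1L, function(k) origin + k * spacing * dir,
           numeric(3)))
}

#' @rdname synthetic_backbones
#' @param z0,z1 start and end height of the helix axis.
#' @param radius helix radius.
#' @param phase phase offset in radians.
#' @param center x/y position of the helix axis.
#' @export
synth_tm_helix <- function(z0, z1, radius = 2.3, rise = 1.5, phase = 0,
                           center = c(0, 0)) {
  n <- round(abs(z1 - z0) / rise) + 1L
  zs <- seq(z0, z1, length.out = n)
  ang <- phase + (seq_len(n) - 1L) * 100 * pi / 180
  cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang), zs)
}

#' @rdname synthetic_backbones
#' @param edge cube edge length.
#' @export
synth_cube <- function(edge = 10, origin = c(0, 0, 0)) {
  corners <- as.matrix(expand.grid(c(0, edge), c(0, edge), c(0, edge)))
  dimnames(corners) <- NULL
  sweep(corners, 2, origin, "+")
}

AA3 <- stats::setNames(
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"),
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"))

random_aa_sequence <- function(n) {
  paste(sample(names(AA3), n, replace = TRUE), collapse = "")
}

#' Write a fixture coordinate file
#'
#' Emits a minimal but standard-conformant PDB (or mmCIF) file from a CA
#' table, with optional dummy membrane atoms (residue `DUM`, as in OPM
#' output) and optional extra side-chain atoms (e.g. cysteine SG).
#'
#' @param atoms data frame `chain`, `resno`, `aa` (1-letter), `x`, `y`,
#'   `z`, optional `b`.
#' @param path output file; format chosen by extension (`.pdb` / `.cif`).
#' @param dum_points optional matrix of dummy membrane atom coordinates.
#' @param extra_atoms optional data frame `chain`, `resno`, `aa`, `elety`,
#'   `x`, `y`, `z` for additional atoms.
#' @param entity_of_chain named character vector chain -> entity id
#'   (mmCIF only).
#' @return `path`, invisibly.
#' @export
write_structure_fixture <- function(atoms, path, dum_points = NULL,
                                    extra_atoms = NULL,
                                    entity_of_chain = NULL) {
  b <- if ("b" %in% names(atoms)) atoms$b else rep(0, nrow(atoms))
  if (grepl("\\.cif$", path)) {
    if (is.null(entity_of_chain)) {
      seqs <- vapply(split(atoms$aa, atoms$chain), paste, character(1),
                     collapse = "")
      entity_of_chain <- stats::setNames(
        as.character(match(seqs, unique(seqs))), names(seqs))
    }
    lines <- c("data_fixture", "#", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_alt_id", "_atom_site.label_comp_id",
               "_atom_site.label_asym_id", "_atom_site.label_entity_id",
               "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y",
               "_atom_site.Cartn_z", "_atom_site.occupancy",
               "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
               "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
               "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
               "_atom_site.pdbx_PDB_model_num")
    for (i in seq_len(nrow(atoms))) {
      res3 <- AA3[[atoms$aa[i]]]
      lines <- c(lines, sprintf(
        "ATOM %d C CA . %s %s %s %d ? %.3f %.3f %.3f 1.00 %.2f ? %d %s %s CA 1",
        i, res3, atoms$chain[i], entity_of_chain[[atoms$chain[i]]],
        atoms$resno[i], atoms$x[i], atoms$y[i], atoms$z[i], b[i],
        atoms$resno[i], res3, atoms$chain[i]))
    }
    lines <- c(lines, "#")
    writeLines(lines, path)
    return(invisible(path))
  }
  fmt <- "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00%6.2f           %s"
  lines <- character(0)
  serial <- 0L
  for (ch in unique(atoms$chain)) {
    sub <- atoms[atoms$chain == ch, , drop = FALSE]
    bs <- b[atoms$chain == ch]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(fmt, serial, " CA ", AA3[[sub$aa[i]]], ch,
                                sub$resno[i], sub$x[i], sub$y[i], sub$z[i],
                                bs[i], "C"))
    }
    if (!is.null(extra_atoms)) {
      ex <- extra_atoms[extra_atoms$chain == ch, , drop = FALSE]
      for (i in seq_len(nrow(ex))) {
        serial <- serial + 1L
        lines <- c(lines, sprintf(fmt, serial,
                                  sprintf(" %-3s", ex$elety[i]),
                                  AA3[[ex$aa[i]]], ch, ex$resno[i],
                                  ex$x[i], ex$y[i], ex$z[i], 0, "S"))
      }
    }
    lines <- c(lines, "TER")
  }
  if (!is.null(dum_points)) {
    for (i in seq_len(nrow(dum_points))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "HETATM%5d  O   DUM  %4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
        serial, 9000 + i, dum_points[i, 1], dum_points[i, 2],
        dum_points[i, 3]))
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Build a synthetic structure with planted ground truth
#'
#' Writes a coordinate file for a set of chains (each a named coordinate
#' matrix plus sequence) and returns the truth the generator knows by
#' construction: analytic hull volumes for cube-shaped subunits, planted
#' membrane planes, and the per-residue geometry.  Optional Gaussian
#' coordinate noise is applied with the supplied RNG seed.
#'
#' @param structure_id identifier (also the file stem).
#' @param chains named list: chain id -> list(`coords` matrix, `seq`
#'   string); sequence length must equal `nrow(coords)`.
#' @param dir output directory.
#' @param format `"pdb"` or `"cif"`.
#' @param b B-factor value for all atoms (e.g. model confidence).
#' @param noise_sigma coordinate noise standard deviation in angstroms.
#' @param seed RNG seed for the noise.
#' @param dum_points optional dummy-membrane-atom matrix.
#' @return List with `file`, `structure_id`, `chains`, and the applied
#'   `noise_sigma`.
#' @export
make_synthetic_structure <- function(structure_id, chains, dir,
                                     format = c("pdb", "cif"), b = 0,
                                     noise_sigma = 0, seed = 1,
                                     dum_points = NULL) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (ch in names(chains)) {
    co <- chains[[ch]]$coords
    sq <- strsplit(chains[[ch]]$seq, "")[[1]]
    if (length(sq) != nrow(co))
      stop("chain ", ch, ": sequence length != coordinate rows")
    rows[[ch]] <- data.frame(chain = ch, resno = seq_len(nrow(co)),
                             aa = sq, x = co[, 1], y = co[, 2], z = co[, 3],
                             b = b, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  if (noise_sigma > 0) {
    rng <- set_local_seed(seed)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, noise_sigma)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, noise_sigma)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, noise_sigma)
  }
  file <- file.path(dir, paste0(structure_id, ".", format))
  write_structure_fixture(atoms, file, dum_points = dum_points)
  list(file = file, structure_id = structure_id, chains = chains,
       noise_sigma = noise_sigma)
}

set_local_seed <- function(seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
}

# --- proteome bundle -------------------------------------------------------

membrane_protein_chain <- function(n_tm, half_thickness, x0 = 0,
                                   loop_len = 5L, loop_gap = 4) {
  h <- half_thickness
  coords <- matrix(numeric(0), 0, 3)
  topo <- character(0)
  add <- function(m, lab) {
    coords <<- rbind(coords, m)
    topo <<- c(topo, rep(lab, nrow(m)))
  }
  # N-terminal loop on the +z side
  add(synth_line(loop_len, origin = c(x0 - 4, 3, h + loop_gap),
                 dir = c(1, 0.2, 0.15)), "O")
  for (i in seq_len(n_tm)) {
    up <- i %% 2 == 0
    cz <- if (up) c(-h, h) else c(h, -h)
    add(synth_tm_helix(cz[1], cz[2], phase = i * 1.1,
                       center = c(x0 + (i - 1) * 7, 0)), "M")
    lab <- if (up) "O" else "I"
    zl <- if (up) h + loop_gap else -h - loop_gap
    add(synth_line(loop_len, origin = c(x0 + (i - 1) * 7 + 2, 4, zl),
                   dir = c(0.6, 0.8, if (up) 0.1 else -0.1)), lab)
  }
  list(coords = coords, topo = paste(topo, collapse = ""))
}

uniprot_block <- function(gene_id, features) {
  lines <- c(sprintf("ID   %s              Reviewed; fixture.", gene_id))
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    rng <- if (f$start == f$end) sprintf("%d", f$start) else
      sprintf("%d..%d", f$start, f$end)
    lines <- c(lines, sprintf("FT   %-15s %s", f$kind, rng))
    if (!is.na(f$note))
      lines <- c(lines, sprintf("FT                   /note=\"%s\"", f$note))
  }
  c(lines, "//")
}

#' Generate a complete synthetic proteome bundle
#'
#' Writes, under `dir`, every input the pipeline consumes -- gene FASTA,
#' complex-target TSV, coordinate files with a manifest and candidate
#' gene-structure pairs, SWISS model metrics, gene metadata, UniProt-style
#' feature text, DeepTMHMM-style topology, an OPM-style file with dummy
#' membrane atoms, mutation and flux tables, and a manual-orientation
#' table -- plus a machine-readable truth bundle (`truth.json`) recording
#' what was planted: per-residue compartments for every structure,
#' expected matching representation per complex, expected curation case
#' per gene, planted membrane planes, and analytic subunit volumes.
#'
#' The roster covers the pipeline's decision space: soluble proteins for
#' each keyword compartment, membrane-associated proteins, oriented
#' inner- and outer-membrane proteins (one backed by OPM dummy atoms),
#' an unoriented membrane protein, a heterodimer matched by a single
#' structure, a complex only coverable by combining monomeric models, an
#' unmatched complex that must fall through to a de novo request, and
#' genes planted to trigger each structure-guided reannotation case.
#'
#' @param dir output directory (created).
#' @param seed RNG seed; identical seeds give byte-identical bundles.
#' @param noise_sigma coordinate noise in angstroms (default 0:
#'   noiseless, so planted truths are exact).
#' @return List with `paths` (named file paths) and `truth`.
#' @export
make_synthetic_proteome <- function(dir, seed = 1, noise_sigma = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sdir <- file.path(dir, "structures")
  dir.create(sdir, showWarnings = FALSE)
  odir <- file.path(dir, "opm")
  dir.create(odir, showWarnings = FALSE)
  set_local_seed(seed)

  genes <- list()     # gene_id -> sequence
  meta <- list()      # gene_id -> list(go, ecocyc, gem)
  targets <- list()   # complex_id -> stoichiometry string
  manifest <- list()  # structure_id -> list(file, source)
  candidates <- list()# rows (structure_id, gene_id)
  metrics <- list()   # rows (structure_id, metric, value)
  up_feats <- list()  # gene_id -> features df
  tm_topo <- character(0)
  truth <- list(compartments = list(), matching = list(), curation = list(),
                planes = list(), volumes = list())

  add_gene <- function(gid, seq, go = "", ecocyc = "", gem = "") {
    genes[[gid]] <<- seq
    meta[[gid]] <<- list(go = go, ecocyc = ecocyc, gem = gem)
  }
  add_structure <- function(sid, chains, source, format = "pdb", b = 90,
                            dum = NULL, cand = names(chains)) {
    st <- make_synthetic_structure(sid, chains, sdir, format = format, b = b,
                                   noise_sigma = noise_sigma,
                                   seed = seed + length(manifest),
                                   dum_points = dum)
    manifest[[sid]] <<- list(file = st$file, source = source)
    for (g in unique(vapply(chains, `[[`, character(1), "gene")))
      candidates[[length(candidates) + 1L]] <<-
        data.frame(structure_id = sid, gene_id = g, stringsAsFactors = FALSE)
    st
  }
  globule_chain <- function(gid, n = 27, origin = c(0, 0, 0)) {
    list(coords = synth_globule(n, origin = origin), seq = genes[[gid]],
         gene = gid)
  }

  # ---- soluble keyword fixtures
  sol <- list(
    list(id = "CPX_CYT1", gid = "gCYT1", ecocyc = "cytosol", cmpt = 12),
    list(id = "CPX_CYT2", gid = "gCYT2", ecocyc = "cytoplasm", cmpt = 12),
    list(id = "CPX_CYT3", gid = "gCYT3", ecocyc = "cytoplasm", cmpt = 12),
    list(id = "CPX_PERI1", gid = "gPERI1", ecocyc = "periplasmic space",
         cmpt = 6),
    list(id = "CPX_PERI2", gid = "gPERI2", ecocyc = "periplasm", cmpt = 6),
    list(id = "CPX_EXT1", gid = "gEXT1", ecocyc = "extracellular",
         cmpt = 1),
    list(id = "CPX_UNK1", gid = "gUNK1", ecocyc = "", cmpt = 19),
    list(id = "CPX_UNK2", gid = "gUNK2", ecocyc = "", cmpt = 19))
  for (s in sol) {
    add_gene(s$gid, random_aa_sequence(27), ecocyc = s$ecocyc)
    targets[[s$id]] <- sprintf("%s:1", s$gid)
    sid <- paste0("S_", s$id)
    add_structure(sid, stats::setNames(list(globule_chain(s$gid)), "A"),
                  "ALPHAFOLD")
    truth$compartments[[sid]] <- rep(s$cmpt, 27)
    truth$matching[[s$id]] <- "SINGLE"
  }

  # ---- membrane-associated (keyword) fixtures: no viable slab
  assoc <- list(
    list(id = "CPX_ASC_C", gid = "gASC1", ecocyc = "inner membrane, cytoplasm",
         cmpt = 11),
    list(id = "CPX_ASC_P", gid = "gASP1", ecocyc = "inner membrane, periplasmic",
         cmpt = 7),
    list(id = "CPX_ASC_PO", gid = "gASP2",
         ecocyc = "outer membrane, periplasmic", cmpt = 5),
    list(id = "CPX_MEM18", gid = "gM18", ecocyc = "membrane", cmpt = 18))
  for (s in assoc) {
    add_gene(s$gid, random_aa_sequence(27), ecocyc = s$ecocyc)
    targets[[s$id]] <- sprintf("%s:1", s$gid)
    sid <- paste0("S_", s$id)
    add_structure(sid, stats::setNames(list(globule_chain(s$gid)), "A"),
                  "ALPHAFOLD")
    truth$compartments[[sid]] <- rep(s$cmpt, 27)
    truth$matching[[s$id]] <- "SINGLE"
  }

  # ---- oriented membrane proteins
  h <- 15  # half-thickness: planted slab is 30 A thick
  mem_fixture <- function(cpx, gid, sid, side_pos, side_neg, ecocyc,
                          with_topo_dom = TRUE, with_opm = FALSE,
                          emb_id, pos_id, neg_id) {
    mp <- membrane_protein_chain(4, h)
    n <- nrow(mp$coords)
    add_gene(gid, random_aa_sequence(n), ecocyc = ecocyc)
    targets[[cpx]] <<- sprintf("%s:1", gid)
    ch <- list(coords = mp$coords, seq = genes[[gid]], gene = gid)
    dum <- NULL
    if (with_opm) {
      grid <- as.matrix(expand.grid(seq(-5, 26, by = 7), seq(-6, 6, by = 4)))
      dum <- rbind(cbind(grid, h), cbind(grid, -h))
    }
    add_structure(sid, list(A = ch), "PDB", dum = NULL)
    if (with_opm)
      write_structure_fixture(
        data.frame(chain = "A", resno = seq_len(n),
                   aa = strsplit(genes[[gid]], "")[[1]],
                   x = mp$coords[, 1], y = mp$coords[, 2], z = mp$coords[, 3],
                   b = 0, stringsAsFactors = FALSE),
        file.path(odir, paste0(sid, ".pdb")), dum_points = dum)
    # UniProt features from the planted topology
    reg <- topology_regions(mp$topo)
    fts <- list()
    for (i in seq_len(nrow(reg))) {
      r <- reg[i, ]
      if (r$type == "M") {
        fts[[length(fts) + 1L]] <- data.frame(
          kind = "TRANSMEM", start = r$start, end = r$end,
          note = "Helical", stringsAsFactors = FALSE)
      } else if (with_topo_dom) {
        lab <- if (r$type == "O") side_pos else side_neg
        fts[[length(fts) + 1L]] <- data.frame(
          kind = "TOPO_DOM", start = r$start, end = r$end, note = lab,
          stringsAsFactors = FALSE)
      }
    }
    up_feats[[gid]] <<- do.call(rbind, fts)
    tm_topo[gid] <<- mp$topo
    z <- mp$coords[, 3]
    truth$compartments[[sid]] <<-
      ifelse(abs(z) <= h, emb_id, ifelse(z > h, pos_id, neg_id))
    truth$matching[[cpx]] <<- "SINGLE"
    truth$planes[[sid]] <<- list(normal = c(0, 0, 1), thickness = 2 * h)
  }
  mem_fixture("CPX_IM1", "gIM1", "S_CPX_IM1", "Periplasmic", "Cytoplasmic",
              "inner membrane", emb_id = 9, pos_id = 8, neg_id = 10)
  mem_fixture("CPX_IM2", "gIM2", "S_CPX_IM2", "Periplasmic", "Cytoplasmic",
              "inner membrane", with_opm = TRUE,
              emb_id = 9, pos_id = 8, neg_id = 10)
  mem_fixture("CPX_OM1", "gOM1", "S_CPX_OM1", "Extracellular", "Periplasmic",
              "outer membrane", emb_id = 3, pos_id = 2, neg_id = 4)
  # unoriented: transmembrane spans but no topological domains, generic
  # membrane annotation -> unknown-orientation inner-membrane compartments
  mem_fixture("CPX_UNOR1", "gUNOR1", "S_CPX_UNOR1", NA, NA, "membrane",
              with_topo_dom = FALSE, emb_id = 9, pos_id = 16, neg_id = 17)

  # ---- matching fixtures
  add_gene("gHA", random_aa_sequence(30), ecocyc = "cytoplasm")
  add_gene("gHB", random_aa_sequence(34), ecocyc = "cytoplasm")
  targets[["CPX_HET1"]] <- "gHA:1,gHB:1"
  add_structure("S_HET1", list(A = globule_chain("gHA", 30),
                               B = globule_chain("gHB", 30 + 4,
                                                 origin = c(30, 0, 0))),
                "PDB")
  truth$matching[["CPX_HET1"]] <- "SINGLE"
  truth$compartments[["S_HET1"]] <- rep(12, 64)

  add_gene("gMC", random_aa_sequence(27), ecocyc = "cytoplasm")
  add_gene("gMD", random_aa_sequence(27), ecocyc = "cytoplasm")
  targets[["CPX_MULTI1"]] <- "gMC:2,gMD:1"
  add_structure("S_MC", list(A = globule_chain("gMC")), "ALPHAFOLD")
  add_structure("S_MD", list(A = globule_chain("gMD")), "ALPHAFOLD")
  truth$matching[["CPX_MULTI1"]] <- "MULTI"
  truth$compartments[["S_MC"]] <- rep(12, 27)
  truth$compartments[["S_MD"]] <- rep(12, 27)

  add_gene("gDE", random_aa_sequence(40), ecocyc = "cytoplasm")
  add_gene("gDF", random_aa_sequence(45), ecocyc = "cytoplasm")
  targets[["CPX_DENOVO1"]] <- "gDE:1,gDF:1"
  add_structure("S_DE", list(A = globule_chain("gDE", 40)), "ALPHAFOLD")
  truth$matching[["CPX_DENOVO1"]] <- "DENOVO"
  truth$compartments[["S_DE"]] <- rep(12, 40)

  # homodimer with planted functional domain and mutations
  add_gene("gH", random_aa_sequence(27), ecocyc = "cytoplasm")
  targets[["CPX_DIMER1"]] <- "gH:2"
  add_structure("S_DIMER1",
                list(A = globule_chain("gH"),
                     B = globule_chain("gH", origin = c(25, 0, 0))),
                "PDB")
  truth$matching[["CPX_DIMER1"]] <- "SINGLE"
  truth$compartments[["S_DIMER1"]] <- rep(12, 54)
  up_feats[["gH"]] <- data.frame(kind = "ACT_SITE", start = 5, end = 5,
                                 note = "fixture site",
                                 stringsAsFactors = FALSE)

  # cube-subunit complex with analytic hull volume (edge 10 -> 1000 A^3)
  add_gene("gCUBE", random_aa_sequence(8), ecocyc = "cytoplasm")
  targets[["CPX_CUBE1"]] <- "gCUBE:1"
  add_structure("S_CUBE1",
                list(A = list(coords = synth_cube(10), seq = genes[["gCUBE"]],
                              gene = "gCUBE")),
                "ALPHAFOLD")
  truth$matching[["CPX_CUBE1"]] <- "SINGLE"
  truth$volumes[["CPX_CUBE1"]] <- 1000
  truth$compartments[["S_CUBE1"]] <- rep(12, 8)

  # ---- curation fixtures (genes outside every annotated complex)
  oligomer_structure <- function(sid, gid, k, source, b = 90) {
    chains <- lapply(seq_len(k), function(i)
      globule_chain(gid, origin = c((i - 1) * 25, 0, 0)))
    names(chains) <- LETTERS[seq_len(k)]
    add_structure(sid, chains, source, b = b)
    truth$compartments[[sid]] <<- rep(12, 27 * k)
  }
  pass_metrics <- function(sid) {
    metrics[[length(metrics) + 1L]] <<- data.frame(
      structure_id = sid, metric = c("GMQE", "QMN4", "QSPRD"),
      value = c(0.8, -1, 0.8), stringsAsFactors = FALSE)
  }
  add_gene("gCI", random_aa_sequence(27), ecocyc = "cytoplasm")
  oligomer_structure("S_CI_PDB", "gCI", 4, "PDB")
  oligomer_structure("S_CI_SW", "gCI", 4, "SWISS"); pass_metrics("S_CI_SW")
  truth$curation[["gCI"]] <- "I"

  add_gene("gCII", random_aa_sequence(27), ecocyc = "cytoplasm")
  oligomer_structure("S_CII_SW", "gCII", 2, "SWISS"); pass_metrics("S_CII_SW")
  truth$curation[["gCII"]] <- "II"

  add_gene("gCIII", random_aa_sequence(27), ecocyc = "cytoplasm")
  oligomer_structure("S_CIII_SW", "gCIII", 2, "SWISS")
  pass_metrics("S_CIII_SW")
  oligomer_structure("S_CIII_PDB", "gCIII", 4, "PDB")
  truth$curation[["gCIII"]] <- "III"

  add_gene("gCIV", random_aa_sequence(27), ecocyc = "cytoplasm")
  oligomer_structure("S_CIV_P2", "gCIV", 2, "PDB")
  oligomer_structure("S_CIV_P4", "gCIV", 4, "PDB")
  truth$curation[["gCIV"]] <- "IV"

  # the Case V pair uses disjoint amino-acid alphabets so the heterodimer's
  # chains can never cross-align above the candidate identity floor
  add_gene("gCV", paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I",
                                 "K", "L"), 27, replace = TRUE),
                        collapse = ""), ecocyc = "cytoplasm")
  add_gene("gCVp", paste(sample(c("M", "N", "P", "Q", "R", "S", "T", "V",
                                  "W", "Y"), 31, replace = TRUE),
                         collapse = ""), ecocyc = "cytoplasm")
  add_structure("S_CV_PDB",
                list(A = globule_chain("gCV"),
                     B = globule_chain("gCVp", 31, origin = c(25, 0, 0))),
                "PDB")
  truth$compartments[["S_CV_PDB"]] <- rep(12, 58)
  truth$curation[["gCV"]] <- "V"

  # SWISS evidence failing QC: excluded, so no oligomeric evidence at all
  add_gene("gQC", random_aa_sequence(27), ecocyc = "cytoplasm")
  oligomer_structure("S_QC_SW", "gQC", 2, "SWISS")
  metrics[[length(metrics) + 1L]] <- data.frame(
    structure_id = "S_QC_SW", metric = c("GMQE", "QMN4", "QSPRD"),
    value = c(0.3, -1, 0.8), stringsAsFactors = FALSE)
  truth$curation[["gQC"]] <- "NONE"

  # ---- mutations (on the gH homodimer: planted in/near/far of ACT_SITE 5)
  mutations <- data.frame(
    gene_id = c("gH", "gH", "gH", "gCYT1"),
    position = c(5L, 6L, 22L, 3L),
    ref_aa = c(substr(genes[["gH"]], 5, 5), substr(genes[["gH"]], 6, 6),
               substr(genes[["gH"]], 22, 22), substr(genes[["gCYT1"]], 3, 3)),
    alt_aa = c("W", "A", "R", "G"),
    source = c("ALE", "ALE", "LTEE", "ALLELEOME"),
    occurrence = c(NA, NA, NA, 0.93),
    stringsAsFactors = FALSE)

  # ---- fluxes
  flux <- data.frame(
    complex_id = c("CPX_CUBE1", "CPX_DIMER1", "CPX_IM1"),
    formation_flux = c(2.0, 0.5, 1.25), stringsAsFactors = FALSE)

  # ---- write the bundle
  paths <- list(
    genes = file.path(dir, "genes.fasta"),
    targets = file.path(dir, "targets.tsv"),
    gene_meta = file.path(dir, "gene_meta.tsv"),
    manifest = file.path(dir, "manifest.tsv"),
    candidates = file.path(dir, "candidates.tsv"),
    metrics = file.path(dir, "metrics.tsv"),
    uniprot = file.path(dir, "uniprot.txt"),
    deeptmhmm = file.path(dir, "deeptmhmm.txt"),
    mutations = file.path(dir, "mutations.tsv"),
    flux = file.path(dir, "flux.tsv"),
    manual_orientation = file.path(dir, "manual_orientation.tsv"),
    opm_dir = odir,
    structures_dir = sdir,
    truth = file.path(dir, "truth.json"))

  reg <- gene_registry(names(genes), unlist(genes))
  write_gene_fasta(reg, paths$genes)
  utils::write.table(
    data.frame(complex_id = names(targets),
               stoichiometry = unlist(targets), stringsAsFactors = FALSE),
    paths$targets, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(meta),
               go = vapply(meta, `[[`, character(1), "go"),
               ecocyc = vapply(meta, `[[`, character(1), "ecocyc"),
               gem = vapply(meta, `[[`, character(1), "gem"),
               stringsAsFactors = FALSE),
    paths$gene_meta, sep = "\t", quote = FALSE, row.names = FALSE)
  # manifest paths are relative to the bundle directory, so identical seeds
  # give byte-identical bundles wherever they are written
  utils::write.table(
    data.frame(structure_id = names(manifest),
               file = file.path("structures", basename(
                 vapply(manifest, `[[`, character(1), "file"))),
               source = vapply(manifest, `[[`, character(1), "source"),
               stringsAsFactors = FALSE),
    paths$manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, candidates), paths$candidates,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, metrics), paths$metrics,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  up_lines <- unlist(lapply(names(up_feats), function(g)
    uniprot_block(g, up_feats[[g]])))
  writeLines(up_lines, paths$uniprot)
  tm_lines <- unlist(lapply(names(tm_topo), function(g)
    c(sprintf(">%s | TM", g), genes[[g]], tm_topo[[g]])))
  writeLines(tm_lines, paths$deeptmhmm)
  utils::write.table(mutations, paths$mutations, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(flux, paths$flux, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(structure_id = character(), side_pos = character(),
               side_neg = character(), stringsAsFactors = FALSE),
    paths$manual_orientation, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(paths = paths, truth = truth)
}
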