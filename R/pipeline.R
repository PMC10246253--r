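#' Default pipeline configuration
#'
#' All tunable thresholds at their standard values: the SWISS QC quadruple
#' (GMQE 0.5, QMN4 -4, QSPRD 0.5, identity 0.7), the 70% single-structure
#' preference, membrane viability (35 degrees, 12-45 angstrom thickness,
#' 10,000 square-angstrom area), the 5% variance stop of the iterative
#' plane fit, interface thresholds 3/5/7.5/10 angstroms, 3 angstrom
#' disulfide cutoff, Grantham severity boundary 100, the 2000-amino-acid
#' de novo bound, and the 3.8 angstrom proximity cutoff.
#'
#' @return Named list of configuration defaults; input paths are `NULL`
#'   and must be supplied (e.g. from [make_synthetic_proteome()]'s
#'   `paths`).
#' @export
default_run_config <- function() {
  list(
    genes = NULL, targets = NULL, gene_meta = NULL, manifest = NULL,
    candidates = NULL, metrics = NULL, uniprot = NULL, deeptmhmm = NULL,
    mutations = NULL, flux = NULL, manual_orientation = NULL,
    manual_curation = NULL, opm_dir = NULL, out_dir = "oligoscape_out",
    seed = 1, force_rerun = FALSE,
    min_candidate_identity = 0.2, single_cutoff = 0.70,
    max_angle = 35, thick_range = c(12, 45), max_area = 10000,
    var_tol = 0.05, interface_thresholds = c(3, 5, 7.5, 10),
    disulfide_cutoff = 3, severe_cutoff = 100, de_novo_max_aa = 2000,
    proximity_cutoff = 3.8)
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override [default_run_config()].
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  user <- yaml::read_yaml(path)
  for (k in names(user)) cfg[[k]] <- user[[k]]
  cfg
}

string_md5 <- function(x) {
  f <- tempfile()
  writeLines(x, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

cache_io <- function(cache_dir, stage, key, force, compute) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(cache_dir, paste0(stage, ".rds"))
  kf <- file.path(cache_dir, paste0(stage, ".key"))
  if (!force && file.exists(f) && file.exists(kf) &&
      identical(readLines(kf, warn = FALSE)[1], key))
    return(readRDS(f))
  val <- compute()
  saveRDS(val, f)
  writeLines(key, kf)
  val
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Stage order: gene/target registry, structure catalog (parsing, trimming,
#' alignment, QC), pseudo-structure enumeration, structure-guided
#' stoichiometry curation, complex matching and representative selection
#' (with de novo requests for the unmatched), membrane compartmentalization
#' of every structure, 3D annotation (mutation proximity, interfaces,
#' disulfides), and geometric flux allocation.  Stages are cached in
#' `out_dir/cache`, keyed on the digest of the input files and thresholds;
#' `force_rerun = TRUE` ignores the cache.  All report tables are written
#' to `out_dir` deterministically, so identical inputs give byte-identical
#' bundles.
#'
#' @param config configuration list (see [default_run_config()]).
#' @return Invisibly, a list with all stage results and `outputs` (named
#'   paths of the written report files).
#' @export
run_pipeline <- function(config = default_run_config()) {
  cfg <- utils::modifyList(default_run_config(), config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cache_dir <- file.path(out_dir, "cache")
  in_files <- unlist(cfg[c("genes", "targets", "gene_meta", "manifest",
                           "candidates", "metrics", "uniprot", "deeptmhmm",
                           "mutations", "flux", "manual_orientation",
                           "manual_curation")])
  in_files <- in_files[!is.na(in_files) & file.exists(in_files)]
  base_key <- string_md5(paste(c(tools::md5sum(sort(in_files)),
                                 utils::capture.output(utils::str(cfg))),
                               collapse = "\n"))
  ck <- function(stage) paste(stage, base_key, sep = ":")
  msg <- function(...) message("[oligoscape] ", ...)

  # ---- stage 1: registry
  reg_stage <- cache_io(cache_dir, "registry", ck("registry"),
                        cfg$force_rerun, function() {
    registry <- read_gene_fasta(cfg$genes)
    annotated <- load_complex_targets(cfg$targets, registry)
    targets <- infer_monomer_targets(registry, annotated)
    list(registry = registry, targets = targets)
  })
  registry <- reg_stage$registry
  targets <- reg_stage$targets
  msg(nrow(registry), " genes, ", length(targets), " targets (",
      sum(vapply(targets, function(t) t$provenance == "EXPECTED_MONOMER",
                 logical(1))), " expected monomers)")

  # ---- stage 2: catalog
  catalog <- cache_io(cache_dir, "catalog", ck("catalog"),
                      cfg$force_rerun, function() {
    man <- utils::read.delim(cfg$manifest, stringsAsFactors = FALSE)
    rel <- !file.exists(man$file)
    man$file[rel] <- file.path(dirname(cfg$manifest), man$file[rel])
    metrics <- if (!is.null(cfg$metrics) && file.exists(cfg$metrics))
      read_model_metrics(cfg$metrics) else list()
    cand <- utils::read.delim(cfg$candidates, stringsAsFactors = FALSE)
    records <- list()
    alignments <- list()   # sid -> entity -> list of alignments
    qc <- list()
    for (i in seq_len(nrow(man))) {
      sid <- man$structure_id[i]
      rec <- parse_structure(man$file[i], man$source[i], sid,
                             model_metrics = metrics[[sid]])
      if (rec$source == "ITASSER") rec <- trim_itasser(rec)
      if (isTRUE(rec$unusable)) next
      records[[sid]] <- rec
      cg <- cand$gene_id[cand$structure_id == sid]
      per_ent <- list()
      best <- NULL
      for (e in rec$entities) {
        als <- list()
        for (g in cg) {
          al <- align_gene_to_chain(registry[g, ], e, sid,
                                    cfg$min_candidate_identity)
          if (!al$low_identity) als[[length(als) + 1L]] <- al
          if (is.null(best) || al$identity > best$identity) best <- al
        }
        per_ent[[e$entity_id]] <- als
      }
      alignments[[sid]] <- per_ent
      qc[[sid]] <- qc_model(rec, best)
    }
    list(records = records, alignments = alignments, qc = qc)
  })
  records <- catalog$records
  msg(length(records), " structures parsed")

  # ---- stage 3: pseudo-structures
  pss <- cache_io(cache_dir, "pseudo", ck("pseudo"), cfg$force_rerun,
                  function() {
    all <- list()
    for (sid in sort(names(records))) {
      ps <- enumerate_pseudo_structures(records[[sid]],
                                        catalog$alignments[[sid]], registry)
      all <- c(all, ps)
    }
    dedupe_best(all)
  })
  msg(length(pss), " pseudo-structures after deduplication")

  # ---- stage 4: curation
  curation <- cache_io(cache_dir, "curation", ck("curation"),
                       cfg$force_rerun, function() {
    monomer_genes <- sort(unique(unlist(lapply(targets, function(t)
      if (length(t$stoichiometry) == 1L && t$stoichiometry == 1L)
        names(t$stoichiometry)))))
    decisions <- lapply(monomer_genes, function(g)
      classify_case(collect_evidence(g, pss, catalog$qc)))
    applied <- apply_curation(targets, decisions, cfg$manual_curation,
                              registry)
    list(decisions = decisions, targets = applied$targets,
         report = applied$report)
  })
  targets <- curation$targets
  msg(sum(curation$report$resolution %in% c("auto", "manual")),
      " stoichiometries reannotated")

  # ---- stage 5: matching
  matching <- cache_io(cache_dir, "matching", ck("matching"),
                       cfg$force_rerun, function() {
    reps <- list(); unmatched <- list(); rows <- list()
    for (t in targets) {
      ms <- match_complex(t, pss, registry)
      if (length(ms) == 0) {
        unmatched[[t$complex_id]] <- t
        rows[[t$complex_id]] <- data.frame(
          complex_id = t$complex_id, representation = "NONE",
          n_parts = 0L, quality = NA_real_, parts = "",
          aborted = isTRUE(attr(ms, "aborted")), stringsAsFactors = FALSE)
        next
      }
      rep <- select_representative(ms, cfg$single_cutoff)
      reps[[t$complex_id]] <- rep
      rows[[t$complex_id]] <- data.frame(
        complex_id = t$complex_id, representation = rep$representation,
        n_parts = rep$n_parts, quality = rep$match_quality,
        parts = rep$key, aborted = FALSE, stringsAsFactors = FALSE)
    }
    requests <- build_de_novo_requests(unmatched, registry,
                                       dir = file.path(out_dir, "de_novo"),
                                       max_aa = cfg$de_novo_max_aa)
    # report paths relative to the output directory for reproducible bundles
    requests$fasta <- ifelse(is.na(requests$fasta), requests$fasta,
                             file.path("de_novo", basename(requests$fasta)))
    list(representatives = reps, unmatched = unmatched,
         table = do.call(rbind, rows[sort(names(rows))]),
         de_novo = requests)
  })
  msg(length(matching$representatives), " complexes matched, ",
      length(matching$unmatched), " queued for de novo prediction")

  # ---- per-structure representative assignment (best pseudo-structure)
  rep_ps <- list()
  for (p in pss) {
    cur <- rep_ps[[p$structure_id]]
    if (is.null(cur) || p$quality > cur$quality) rep_ps[[p$structure_id]] <- p
  }

  # ---- stage 6: membrane & compartments
  membrane <- cache_io(cache_dir, "membrane", ck("membrane"),
                       cfg$force_rerun, function() {
    meta <- utils::read.delim(cfg$gene_meta, stringsAsFactors = FALSE)
    rownames(meta) <- meta$gene_id
    upf <- if (!is.null(cfg$uniprot) && file.exists(cfg$uniprot))
      parse_uniprot_features(cfg$uniprot) else NULL
    tmh <- if (!is.null(cfg$deeptmhmm) && file.exists(cfg$deeptmhmm))
      parse_deeptmhmm(cfg$deeptmhmm) else NULL
    manual <- if (!is.null(cfg$manual_orientation) &&
                  file.exists(cfg$manual_orientation))
      utils::read.delim(cfg$manual_orientation, stringsAsFactors = FALSE)
    else NULL
    structure_genes <- lapply(rep_ps, function(p) unique(p$assignment))
    cand_ids <- flag_membrane_candidates(structure_genes, meta, upf)
    comp <- list(); assess <- list(); rows <- list()
    for (sid in sort(names(records))) {
      rec <- records[[sid]]
      p <- rep_ps[[sid]]
      if (is.null(p)) next
      als <- p$alignments
      genes <- unique(p$assignment)
      gm <- meta[intersect(genes, rownames(meta)), , drop = FALSE]
      chosen <- NULL; orientation <- NULL
      if (sid %in% cand_ids) {
        opm_file <- if (!is.null(cfg$opm_dir))
          file.path(cfg$opm_dir, paste0(sid, ".pdb")) else ""
        opm <- if (nzchar(opm_file) && file.exists(opm_file))
          parse_opm(opm_file) else NULL
        gupf <- if (!is.null(upf))
          upf[upf$gene_id %in% genes, , drop = FALSE] else NULL
        sets <- build_crossing_sets(rec, als, gupf, tmh, opm)
        assessments <- lapply(sets, assess_crossing_set, record = rec,
                              max_angle = cfg$max_angle,
                              thick_range = cfg$thick_range,
                              max_area = cfg$max_area)
        chosen <- choose_source(assessments)
        if (!is.null(chosen))
          orientation <- orient_protein(rec, chosen, als, gupf, manual)
      }
      ca <- assign_compartments(rec, gm, chosen, orientation,
                                membrane_candidate = sid %in% cand_ids)
      ca$structure_id <- sid
      comp[[sid]] <- ca
      assess[[sid]] <- chosen
      rows[[sid]] <- data.frame(
        structure_id = sid, membrane_candidate = sid %in% cand_ids,
        viable = !is.null(chosen),
        source = if (is.null(chosen)) NA_character_ else chosen$source,
        thickness = if (is.null(chosen)) NA_real_ else chosen$thickness_A,
        oriented = !is.null(orientation) && isTRUE(orientation$known),
        stringsAsFactors = FALSE)
    }
    list(compartments = do.call(rbind, comp), assessments = assess,
         summary = do.call(rbind, rows))
  })
  msg(nrow(membrane$compartments), " residues assigned to compartments")

  # ---- stage 7: annotation
  annotation <- cache_io(cache_dir, "annotation", ck("annotation"),
                         cfg$force_rerun, function() {
    upf <- if (!is.null(cfg$uniprot) && file.exists(cfg$uniprot))
      parse_uniprot_features(cfg$uniprot) else NULL
    muts <- if (!is.null(cfg$mutations) && file.exists(cfg$mutations))
      read_mutations(cfg$mutations) else NULL
    prox <- list(); ifaces <- list(); ss <- list()
    dom <- NULL
    if (!is.null(upf)) {
      fun <- upf[!upf$kind %in% c("TRANSMEM", "TOPO_DOM", "INTRAMEM"), ,
                 drop = FALSE]
      if (nrow(fun))
        dom <- do.call(rbind, lapply(seq_len(nrow(fun)), function(i)
          data.frame(gene_id = fun$gene_id[i], kind = fun$kind[i],
                     position = fun$start[i]:fun$end[i],
                     stringsAsFactors = FALSE)))
    }
    for (sid in sort(names(records))) {
      rec <- records[[sid]]
      p <- rep_ps[[sid]]
      if (is.null(p)) next
      if (!is.null(muts) && !is.null(dom)) {
        mu <- muts[muts$gene_id %in% p$assignment, , drop = FALSE]
        dm <- dom[dom$gene_id %in% p$assignment, , drop = FALSE]
        if (nrow(mu) && nrow(dm)) {
          pr <- proximity_report(mu, dm, rec, p$alignments,
                                 cutoff = cfg$proximity_cutoff,
                                 severe_cutoff = cfg$severe_cutoff)
          pr$structure_id <- sid
          prox[[sid]] <- pr
        }
      }
      for (th in cfg$interface_thresholds) {
        r <- detect_interfaces(rec, th)$residues
        if (nrow(r)) {
          r$threshold <- th
          r$structure_id <- sid
          ifaces[[paste(sid, th)]] <- r
        }
      }
      d <- detect_disulfides(rec, cfg$disulfide_cutoff)
      if (nrow(d)) {
        d$structure_id <- sid
        ss[[sid]] <- d
      }
    }
    bind0 <- function(l) if (length(l)) do.call(rbind, l) else NULL
    list(proximity = bind0(prox), interfaces = bind0(ifaces),
         disulfides = bind0(ss))
  })

  # ---- stage 8: geometry & allocation
  geometry <- cache_io(cache_dir, "geometry", ck("geometry"),
                       cfg$force_rerun, function() {
    profiles <- list(); rows <- list()
    for (cid in sort(names(matching$representatives))) {
      m <- matching$representatives[[cid]]
      vol <- 0; area <- NA_real_
      for (p in m$parts) {
        rec <- records[[p$structure_id]]
        pr <- suppressWarnings(protein_volume(rec, cid))
        vol <- vol + pr$total_volume
        if (m$n_parts == 1L) {
          a <- membrane$assessments[[p$structure_id]]
          if (!is.null(a)) {
            pr <- membrane_footprint(rec, a, pr)
            area <- pr$membrane_area
          }
        }
      }
      prof <- structure(list(complex_id = cid, subunit_volumes = NULL,
                             total_volume = vol, membrane_area = area,
                             area_by_plane = c(NA_real_, NA_real_)),
                        class = "geometric_profile")
      profiles[[cid]] <- prof
      rows[[cid]] <- data.frame(complex_id = cid, volume = vol,
                                membrane_area = area, stringsAsFactors = FALSE)
    }
    alloc <- NULL
    if (!is.null(cfg$flux) && file.exists(cfg$flux))
      alloc <- allocate_fluxes(profiles, cfg$flux, targets, registry)
    list(profiles = profiles, table = do.call(rbind, rows),
         allocation = alloc)
  })
  msg(length(geometry$profiles), " geometric profiles computed")

  # ---- reports
  outputs <- list(
    targets = write_tsv(write_complex_targets(targets),
                        file.path(out_dir, "targets_final.tsv")),
    pseudo = write_tsv(write_pseudo_structures(pss),
                       file.path(out_dir, "pseudo_structures.tsv")),
    curation = write_tsv(curation$report,
                         file.path(out_dir, "curation_report.tsv")),
    matches = write_tsv(matching$table, file.path(out_dir, "matches.tsv")),
    de_novo = write_tsv(matching$de_novo,
                        file.path(out_dir, "de_novo_requests.tsv")),
    compartments = write_tsv(membrane$compartments,
                             file.path(out_dir, "compartments.tsv")),
    membrane = write_tsv(membrane$summary,
                         file.path(out_dir, "membrane_summary.tsv")),
    geometry = write_tsv(geometry$table, file.path(out_dir, "geometry.tsv")))
  if (!is.null(annotation$proximity))
    outputs$proximity <- write_tsv(annotation$proximity,
                                   file.path(out_dir, "proximity.tsv"))
  if (!is.null(annotation$interfaces))
    outputs$interfaces <- write_tsv(annotation$interfaces,
                                    file.path(out_dir, "interfaces.tsv"))
  if (!is.null(annotation$disulfides))
    outputs$disulfides <- write_tsv(annotation$disulfides,
                                    file.path(out_dir, "disulfides.tsv"))
  if (!is.null(geometry$allocation))
    outputs$allocation <- write_tsv(geometry$allocation,
                                    file.path(out_dir, "allocation.tsv"))

  invisible(list(config = cfg, registry = registry, targets = targets,
                 records = records, pseudo_structures = pss,
                 curation = curation, matching = matching,
                 membrane = membrane, annotation = annotation,
                 geometry = geometry, outputs = outputs))
}
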