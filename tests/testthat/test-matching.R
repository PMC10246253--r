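match_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(99)
      cache <<- do.call(mk_registry, as.list(stats::setNames(
        replicate(6, rand_seq(20)), paste0("g", 1:6))))
    }
    cache
  }
})

test_that("worked multiset-cover example matches the enumeration", {
  reg <- match_registry()
  target <- complex_target("C", c(g1 = 2L, g2 = 1L))
  parts <- list(S1 = c(g1 = 2L, g2 = 1L), S2 = c(g1 = 1L), S3 = c(g2 = 1L))
  pss <- mapply(mk_ps, names(parts), parts, SIMPLIFY = FALSE)
  ms <- match_complex(target, pss, reg)
  keys <- sort(vapply(ms, `[[`, character(1), "key"))
  expect_equal(keys, sort(c("S1/g1+g2",
                            "S2/g1&S2/g1&S3/g2")))
  for (m in ms) expect_equal(m$covered, target$stoichiometry)
  reps <- stats::setNames(vapply(ms, `[[`, character(1), "representation"),
                          vapply(ms, `[[`, character(1), "key"))
  expect_equal(unname(reps[["S1/g1+g2"]]), "SINGLE")
  expect_equal(unname(reps[["S2/g1&S2/g1&S3/g2"]]), "MULTI")
})

test_that("a single-part match flags SINGLE and exact cover always holds", {
  reg <- match_registry()
  t1 <- complex_target("C1", c(g1 = 1L))
  ms <- match_complex(t1, list(mk_ps("S", c(g1 = 1L))), reg)
  expect_length(ms, 1)
  expect_equal(ms[[1]]$representation, "SINGLE")
  # incomplete catalog -> no match
  t2 <- complex_target("C2", c(g1 = 1L, g2 = 1L))
  expect_length(match_complex(t2, list(mk_ps("S", c(g1 = 1L))), reg), 0)
})

test_that("matching equals the brute-force cover oracle on random instances", {
  reg <- match_registry()
  set.seed(314)
  for (trial in 1:30) {
    n_genes <- sample(1:3, 1)
    genes <- paste0("g", seq_len(n_genes))
    target_st <- stats::setNames(sample(1:3, n_genes, replace = TRUE), genes)
    if (sum(target_st) > 6) target_st <- pmin(target_st, 2L)
    n_parts <- sample(1:8, 1)
    part_sts <- lapply(seq_len(n_parts), function(i) {
      gs <- sample(genes, sample(1:n_genes, 1))
      stats::setNames(sample(1:2, length(gs), replace = TRUE), gs)
    })
    names(part_sts) <- sprintf("P%02d", seq_len(n_parts))
    pss <- mapply(mk_ps, names(part_sts), part_sts, SIMPLIFY = FALSE)
    target <- complex_target("CT", target_st)
    ms <- match_complex(target, pss, reg)
    got <- sort(vapply(ms, `[[`, character(1), "key"))
    # oracle works on the subset of usable parts in the same order
    usable <- Filter(function(i) {
      st <- part_sts[[i]]
      all(names(st) %in% names(target_st)) &&
        all(st <= target_st[names(st)])
    }, seq_len(n_parts))
    oracle <- oracle_multiset_cover(target_st, part_sts[usable])
    want <- sort(vapply(oracle, function(idx)
      paste(sort(vapply(usable[idx], function(i)
        pss[[i]]$ps_id, character(1))), collapse = "&"), character(1)))
    expect_equal(got, want)
    for (m in ms) expect_equal(m$covered, target$stoichiometry)
  }
})

test_that("representative selection follows the ordered preference policy", {
  reg <- match_registry()
  target <- complex_target("C", c(g1 = 2L))
  mk_match <- function(parts) {
    ms <- match_complex(target, parts, reg)
    ms
  }
  # SINGLE above 70% beats a better MULTI
  single75 <- mk_ps("SA", c(g1 = 2L), quality = 0.75)
  mono <- mk_ps("SB", c(g1 = 1L), quality = 0.95, source = "ALPHAFOLD")
  ms <- match_complex(target, list(single75, mono), reg)
  expect_equal(select_representative(ms)$key, "SA/g1")
  # an AF-Multimer single wins even at low quality
  afm <- mk_ps("SC", c(g1 = 2L), quality = 0.6, source = "AF_MULTIMER")
  ms2 <- match_complex(target, list(afm, mono), reg)
  expect_equal(select_representative(ms2)$key, "SC/g1")
  # SINGLE at 0.5 loses to a MULTI at 0.95 (trade-off rule)
  single50 <- mk_ps("SD", c(g1 = 2L), quality = 0.5)
  ms3 <- match_complex(target, list(single50, mono), reg)
  expect_equal(select_representative(ms3)$representation, "MULTI")
  # permuting the input never changes the winner
  set.seed(5)
  all_parts <- list(single75, mono, afm, single50)
  base <- select_representative(match_complex(target, all_parts, reg))$key
  for (i in 1:5) {
    perm <- sample(all_parts)
    expect_equal(select_representative(match_complex(target, perm, reg))$key,
                 base)
  }
  expect_error(select_representative(list()), "no matches")
})

test_that("source priority and part count break quality ties", {
  reg <- match_registry()
  target <- complex_target("C", c(g1 = 2L))
  pdb <- mk_ps("SP", c(g1 = 2L), quality = 0.6, source = "PDB")
  swiss <- mk_ps("SS", c(g1 = 2L), quality = 0.6, source = "SWISS")
  ms <- match_complex(target, list(swiss, pdb), reg)
  expect_equal(select_representative(ms)$sources, "PDB")
  # fewer parts preferred at equal quality
  mono <- mk_ps("SM", c(g1 = 1L), quality = 0.6, source = "ITASSER")
  ms2 <- match_complex(target, list(swiss, mono), reg)
  sel <- select_representative(ms2)
  expect_equal(sel$n_parts, 1L)
})

test_that("de novo requests apply the 2000-amino-acid eligibility bound", {
  reg <- mk_registry(big = paste(rep("A", 1800), collapse = ""),
                     huge = paste(rep("K", 2500), collapse = ""),
                     tiny = "MKTA")
  t1 <- complex_target("C1", c(big = 1L))
  t2 <- complex_target("C2", c(huge = 1L))
  dir <- file.path(tempdir(), "denovo_t")
  req <- build_de_novo_requests(list(t1, t2), reg, dir = dir)
  expect_equal(req$eligible, c(TRUE, FALSE))
  expect_equal(req$total_aa, c(1800, 2500))
  expect_true(all(file.exists(req$fasta)))
  # stoichiometric ratio: one FASTA entry per subunit copy
  t3 <- complex_target("C3", c(tiny = 3L))
  req3 <- build_de_novo_requests(list(t3), reg, dir = dir)
  fa <- Biostrings::readAAStringSet(req3$fasta[1])
  expect_length(fa, 3)
  expect_length(build_de_novo_requests(list(), reg)$complex_id, 0)
})
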