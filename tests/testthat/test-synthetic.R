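test_that("generated dictionaries are sparse, non-negative and seeded", {
  grid <- small_grid(c(4L, 4L, 4L))
  full <- make_grid(c(4L, 4L, 4L), mask = array(TRUE, c(4, 4, 4)))

  d0 <- generate_dictionary(3L, full, sparsity = 0.9, overlap = 0, seed = 1)
  supports <- apply(d0$components, 1L, function(r) which(r != 0))
  # zero overlap forces pairwise disjoint supports
  expect_length(unlist(supports), length(unique(unlist(supports))))
  expect_lt(max(abs(rowMeans(d0$components != 0) - 0.1)), 0.02)

  d7a <- generate_dictionary(5L, grid, seed = 7)
  d7b <- generate_dictionary(5L, grid, seed = 7)
  expect_identical(d7a$components, d7b$components)

  big <- make_grid(c(12L, 12L, 12L))
  d128 <- generate_dictionary(128L, big, sparsity = 0.95, overlap = 0.2,
                              seed = 3)
  expect_true(all(d128$components >= 0))
  expect_true(all(rowSums(d128$components != 0) >= 1))
  expect_true(mean(d128$components == 0) > 0.5)

  expect_error(generate_dictionary(sum(grid$mask) + 1L, grid),
               "between 1 and")
})

test_that("dictionary pyramids nest coarse components over their fine groups", {
  grid <- small_grid(c(10L, 10L, 10L))
  pyr <- generate_dictionary_pyramid(c(24L, 12L, 6L), grid, jitter = 0.3,
                                     seed = 4)
  expect_identical(vapply(pyr, `[[`, 0L, "K"), c(24L, 12L, 6L))
  for (d in pyr) {
    expect_true(all(d$components >= 0))
    expect_true(all(rowSums(d$components != 0) >= 1))
  }
  # each level-2 component aggregates two fine components: their supports
  # are wholly contained in it
  fine_sups <- apply(pyr[[1]]$components != 0, 1L, which, simplify = FALSE)
  for (k in 1:12) {
    sup <- which(pyr[[2]]$components[k, ] != 0)
    contained <- sum(vapply(fine_sups, function(fs) all(fs %in% sup), NA))
    expect_gte(contained, 2L)
  }
  expect_identical(generate_dictionary_pyramid(c(24L, 12L), grid, seed = 9),
                   generate_dictionary_pyramid(c(24L, 12L), grid, seed = 9))
})

test_that("generated ontologies are acyclic forests with resolvable synonyms", {
  o1 <- generate_ontology(1L, seed = 2)
  expect_identical(nrow(o1$concepts), 1L)
  expect_identical(nrow(o1$hypernyms), 0L)

  o <- generate_ontology(40L, n_synonym_pairs = 10L, max_depth = 3L, seed = 5)
  # every ancestor chain has length <= max_depth
  for (cid in o$concepts$id) {
    expect_lte(length(concept_ancestors(o, cid)) + 1L, 3L)
  }
  expect_identical(nrow(o$synonyms), 10L)
  expect_false(anyDuplicated(tolower(o$synonyms$name)) > 0)
  # each synonym resolves to exactly one concept
  expect_true(all(o$synonyms$concept_id %in% o$concepts$id))

  expect_identical(generate_ontology(15L, 3L, 2L, seed = 9),
                   generate_ontology(15L, 3L, 2L, seed = 9))
  expect_error(generate_ontology(5L, n_synonym_pairs = 6L), "exceeds")
  expect_error(
    ontology(data.frame(id = c("a", "b"), name = c("x", "y")),
             hypernyms = data.frame(child = c("a", "b"),
                                    parent = c("b", "a"))),
    "cycle")
})

test_that("concept names contain the names of exactly their ancestors", {
  o <- generate_ontology(300L, seed = 4)
  nm <- stats::setNames(o$concepts$name, o$concepts$id)
  for (cid in sample(o$concepts$id, 40)) {
    contained <- o$concepts$id[o$concepts$id != cid &
      vapply(o$concepts$name, function(other) {
        grepl(paste0("\\b", other, "\\b"), nm[[cid]])
      }, NA)]
    expect_setequal(contained, concept_ancestors(o, cid))
  }
})

test_that("noiseless forward model is exact and annotations verbatim", {
  grid <- small_grid()
  d <- generate_dictionary(10L, grid, sparsity = 0.8, seed = 1)
  ont <- generate_ontology(8L, 0L, max_depth = 1L, seed = 1)  # flat: truth = active
  cfg <- synth_config(
    n_collections = 1L, maps_per_collection = 20L,
    noise_sd = 0, baseline_shift_sd = 0,
    annotation_noise = list(synonym = 0, abbrev = 0, typo = 0, omit = 0),
    contaminant_rates = list(thresholded = 0, low_coverage = 0,
                             wrong_modality = 0),
    map_type_probs = c(z = 1, t = 0, beta = 0), seed = 3)
  maps <- generate_repository(ont, d, cfg)
  sig <- attr(maps, "signatures")
  for (m in maps) {
    expected <- mask_values(back_project(
      cfg$concept_effect_size *
        rowSums(sig[, m$truth_labels, drop = FALSE]), d))
    expect_equal(mask_values(m$volume), expected, tolerance = 1e-12)
    # zero annotation noise: every truth label's canonical name is verbatim
    txt <- paste(unlist(m$annotations), collapse = " ")
    for (cid in m$truth_labels) {
      expect_match(txt, ont$concepts$name[ont$concepts$id == cid],
                   fixed = TRUE)
    }
  }
})

test_that("repositories are seeded, label-closed, and rate-faithful", {
  fx <- standard_fixture()
  maps2 <- generate_repository(fx$ont, fx$dicts, fx$cfg)
  expect_identical(lapply(fx$maps, `[[`, "volume"),
                   lapply(maps2, `[[`, "volume"))
  expect_identical(lapply(fx$maps, `[[`, "annotations"),
                   lapply(maps2, `[[`, "annotations"))

  ids <- vapply(fx$maps, `[[`, "", "map_id")
  expect_false(anyDuplicated(ids) > 0)

  # truth labels closed under hypernymy
  for (m in fx$maps[seq(1, length(fx$maps), by = 7)]) {
    closure <- union(m$truth_labels, concept_ancestors(fx$ont, m$truth_labels))
    expect_setequal(m$truth_labels, closure)
  }

  # contaminant counts within binomial error at n = 1000
  big <- generate_repository(
    fx$ont, fx$dicts[[3L]],
    synth_config(n_collections = 5L, maps_per_collection = 200L,
                 contaminant_rates = list(thresholded = 0.1,
                                          low_coverage = 0.1,
                                          wrong_modality = 0.1),
                 seed = 21))
  flags <- vapply(big, function(m) m$contaminant %||% "none", "")
  n <- length(big)
  for (kind in c("thresholded", "low_coverage", "wrong_modality")) {
    expect_lt(abs(sum(flags == kind) - 0.1 * n),
              4 * sqrt(n * 0.1 * 0.9))
  }
  # thresholded contaminants have > 50% exact zeros in-mask
  thr <- big[flags == "thresholded"]
  expect_true(all(vapply(thr, function(m) {
    mean(mask_values(m$volume) == 0) > 0.5
  }, NA)))
})

test_that("zero noise projection onto the generating dictionary recovers loadings", {
  grid <- small_grid()
  d <- generate_dictionary(12L, grid, sparsity = 0.8, seed = 6)
  ont <- generate_ontology(6L, 0L, 2L, seed = 6)
  cfg <- synth_config(n_collections = 1L, maps_per_collection = 10L,
                      noise_sd = 0, baseline_shift_sd = 0,
                      contaminant_rates = list(thresholded = 0,
                                               low_coverage = 0,
                                               wrong_modality = 0),
                      map_type_probs = c(z = 1, t = 0, beta = 0), seed = 6)
  maps <- generate_repository(ont, d, cfg)
  X <- embed_repository(maps, d, positive = FALSE)
  sig <- attr(maps, "signatures")
  recon <- vapply(maps, function(m) {
    # truth is hypernym-closed; reconstruct the generating loading vector
    # from the signature matrix restricted to the deepest active concepts
    as.numeric(mask_values(back_project(X[m$map_id, ], d)))
  }, numeric(sum(grid$mask)))
  truth_vox <- vapply(maps, function(m) mask_values(m$volume),
                      numeric(sum(grid$mask)))
  expect_equal(recon, truth_vox, tolerance = 1e-8)
})

test_that("repository round-trips through NIfTI + manifests + CSV", {
  fx <- standard_fixture()
  dir <- withr::local_tempdir()
  write_repository(fx$maps[1:12], dir, fx$ont)
  back <- read_repository(dir)
  expect_length(back, 12L)
  ont2 <- attr(back, "ontology")
  expect_equal(ont2$concepts, fx$ont$concepts)
  ids <- vapply(back, `[[`, "", "map_id")
  for (i in seq_along(back)) {
    orig <- fx$maps[[match(ids[i], vapply(fx$maps, `[[`, "", "map_id"))]]
    expect_equal(mask_values(back[[i]]$volume), mask_values(orig$volume),
                 tolerance = 1e-5)        # float32 storage
    expect_identical(back[[i]]$map_type, orig$map_type)
    expect_setequal(back[[i]]$truth_labels %||% character(),
                    orig$truth_labels %||% character())
  }
})
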