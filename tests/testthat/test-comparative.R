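test_that("overlap_sets computes exact Venn regions and Jaccard indices", {
  ov <- overlap_sets(list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"),
                          C = "g3"))
  regions <- setNames(ov$regions$size, ov$regions$region)
  expect_equal(unname(regions["A"]), 1)        # g1
  expect_equal(unname(regions["B"]), 1)        # g4
  expect_equal(unname(regions["A&B"]), 1)      # g2
  expect_equal(unname(regions["A&B&C"]), 1)    # g3
  expect_equal(unname(regions["C"]), 0)
  expect_equal(sum(ov$regions$size), 4)        # union size
  j <- ov$jaccard
  expect_equal(j$jaccard[j$set1 == "A" & j$set2 == "B"], 2 / 4)
  # identical sets
  ov2 <- overlap_sets(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(ov2$jaccard$jaccard, 1)
  expect_equal(sum(ov2$regions$size), 2)
  # disjoint sets: all intersection regions empty
  ov3 <- overlap_sets(list(A = "x", B = "y"))
  expect_equal(ov3$regions$size[ov3$regions$region == "A&B"], 0)
  expect_error(overlap_sets(as.list(setNames(letters[1:5], letters[1:5]))),
               "2-4")
  # region sizes always decompose the union exactly (brute-force check)
  set.seed(8)
  sets <- purrr::map(1:4, ~ sample(letters, sample(5:15, 1)))
  names(sets) <- paste0("S", 1:4)
  ov4 <- overlap_sets(sets)
  expect_equal(sum(ov4$regions$size),
               length(unique(unlist(sets))))
})

test_that("jaccard_index handles edge cases", {
  expect_equal(jaccard_index(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard_index(character(), character()), NA_real_)
  expect_equal(jaccard_index(c("a", "a"), "a"), 1)
})

de_fixture <- function() {
  tibble::tibble(
    gene_id = rep(c("gx", "gy"), each = 5),
    species = "TSD",
    stage = rep(c(9L, 12L, 15L, 19L, 22L), 2),
    tier = c("ns", "ns", "ns", "ns", "stringent",
             "suggestive", "ns", "ns", "suggestive", "suggestive"),
    direction = c("none", "low", "high", "none", "low",
                  "low", "none", "none", "low", "low"),
    p = 0.5, q = 0.5, mean_low = 10, mean_high = 10, log2fc = 0
  )
}

test_that("direction_profile reports direction only at significant stages", {
  prof <- direction_profile(de_fixture(), "gx", "TSD")
  expect_equal(nrow(prof), 5)
  expect_equal(prof$direction, c("ns", "ns", "ns", "ns", "low"))
  # a stage missing from the results is ns
  prof2 <- direction_profile(de_fixture(), "gx", "TSD",
                             stages = c(9L, 12L, 15L, 19L, 22L, 25L))
  expect_equal(nrow(prof2), 6)
  expect_equal(prof2$direction[6], "ns")
  expect_error(direction_profile(de_fixture(), "nope", "TSD"),
               "unknown gene")
})

test_that("direction_concordance counts matches over comparable stages", {
  stages <- c(9L, 12L, 15L, 19L, 22L)
  mk <- function(dirs) tibble::tibble(stage = stages, direction = dirs)
  # identical profiles, 3 comparable stages
  p <- mk(c("low", "high", "ns", "low", "ns"))
  expect_equal(direction_concordance(p, p)$concordance, 1)
  # fully opposite
  q <- mk(c("high", "low", "ns", "high", "ns"))
  expect_equal(direction_concordance(p, q)$concordance, 0)
  # reference (26,31,ns,26,31) vs observed (26,ns,ns,26,26):
  # comparable stages 1, 4, 5; matches at 1 and 4 -> 2/3
  ref <- mk(c("low", "high", "ns", "low", "high"))
  obs <- mk(c("low", "ns", "ns", "low", "low"))
  cc <- direction_concordance(obs, ref)
  expect_equal(sum(cc$per_stage$comparable), 3)
  expect_equal(cc$concordance, 2 / 3)
  # symmetry in the two arguments
  expect_equal(direction_concordance(ref, obs)$concordance, 2 / 3)
  # nothing comparable -> NA
  allns <- mk(rep("ns", 5))
  expect_true(is.na(direction_concordance(p, allns)$concordance))
  # include_ns mode counts joint-ns stages as matches
  expect_equal(direction_concordance(p, p, include_ns = TRUE)$concordance, 1)
  expect_error(direction_concordance(p, mk(c("low", "high", "ns", "low",
                                             "ns"))[1:4, ]),
               "different stage sets")
})

test_that("tag_gene_sets counts DE genes per category with multi-membership", {
  res <- de_fixture()
  catalog <- tibble::tibble(
    set_name = c("HK", "HS", "HS2"),
    gene_id = c("gx", "gy", "gy")
  )
  tags <- tag_gene_sets(res, catalog)
  # gy is suggestive at 3 stages, in both HS and HS2 -> counted in both
  expect_equal(sum(tags$n[tags$set_name == "HS"]), 3)
  expect_equal(sum(tags$n[tags$set_name == "HS2"]), 3)
  expect_equal(sum(tags$n[tags$set_name == "HK"]), 1)
  # empty DE set -> no rows
  res_ns <- dplyr::mutate(res, tier = "ns")
  expect_equal(nrow(tag_gene_sets(res_ns, catalog)), 0)
  # uncategorized fallback
  tags2 <- tag_gene_sets(res, catalog[1, ])
  expect_true("uncategorized" %in% tags2$set_name)
  expect_error(tag_gene_sets(res, catalog[0, ]), "empty")
})

test_that("cross_species_concordance localizes discordance", {
  a <- de_fixture()
  # species B: same calls for gx, opposite direction for gy at stage 19/22
  b <- a |>
    dplyr::mutate(species = "GSD",
                  direction = dplyr::if_else(.data$gene_id == "gy" &
                                               .data$stage >= 19,
                                             "high", .data$direction))
  cc <- cross_species_concordance(a, b, shared = c("gx", "gy"))
  st <- setNames(cc$per_gene$status, cc$per_gene$gene_a)
  expect_equal(unname(st["gx"]), "concordant")
  expect_equal(unname(st["gy"]), "discordant")
  # one species all-ns: nothing comparable
  b_ns <- dplyr::mutate(a, species = "GSD", tier = "ns")
  cc2 <- cross_species_concordance(a, b_ns, shared = c("gx", "gy"))
  expect_true(all(cc2$per_gene$status == "not-comparable"))
  expect_error(cross_species_concordance(a, b,
                                         shared = character()), "empty")
  # two-column mapping with different ids
  b_ren <- dplyr::mutate(b, gene_id = paste0("o_", .data$gene_id))
  cc3 <- cross_species_concordance(
    a, b_ren, shared = tibble::tibble(gene_a = c("gx", "gy"),
                                      gene_b = c("o_gx", "o_gy")))
  expect_equal(nrow(cc3$per_gene), 2)
})
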