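test_that("percent MNI normalizes per context within the chosen scope", {
  mni <- mni_from_matrix(matrix(c(2, 3, 5), 3,
                                dimnames = list(c("a", "b", "c"), "X")))
  p <- percent_mni(mni)
  expect_equal(p$X, c(0.2, 0.3, 0.5))

  # scoped denominators: restricting to {a, b} rescales to the scoped total
  mni2 <- mni_from_matrix(matrix(c(2, 3, 5, 1, 1, 0), 3,
                                 dimnames = list(c("a", "b", "c"), c("X", "Y"))))
  p2 <- percent_mni(mni2, taxa_subset = c("a", "b"))
  expect_equal(p2$X, c(2, 3) / 5)

  # scale invariance: doubling a column leaves proportions unchanged
  mni3 <- mni2
  mni3$X <- mni3$X * 2L
  expect_equal(percent_mni(mni3)$X, percent_mni(mni2)$X)

  # all-zero column is flagged, not silently zeroed
  mni4 <- mni_from_matrix(matrix(c(1, 2, 0, 0), 2,
                                 dimnames = list(c("a", "b"), c("X", "Y"))))
  expect_warning(p4 <- percent_mni(mni4), "flagged")
  expect_true(all(is.na(p4$Y)))
  expect_equal(attr(p4, "flagged_contexts"), "Y")

  expect_error(percent_mni(mni, taxa_subset = "nope"), "Unknown taxon")
})

test_that("percent MNI reproduces the printed Surf Clam Ridge surf-clam share", {
  p <- percent_mni(pineland_mni())
  i <- match("Spisula solidissima", p$taxon_id)
  expect_equal(p[["Surf Clam Ridge (Trench 11B-93)"]][i], 87 / 164)
})

test_that("Shannon diversity matches closed forms and its invariances", {
  expect_equal(shannon_diversity(1), 0)
  for (k in c(2, 5, 17)) {
    expect_equal(shannon_diversity(rep(1 / k, k)), log(k))
  }
  expect_equal(shannon_diversity(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(round(shannon_diversity(c(0.5, 0.25, 0.25)), 5), 1.03972)
  # zero-count taxa carry no information
  expect_equal(shannon_diversity(c(0.5, 0.25, 0.25, 0, 0)),
               shannon_diversity(c(0.5, 0.25, 0.25)))
  expect_error(shannon_diversity(c(0.5, 0.2)), "sum to 1")
  # the uniform column maximizes H among columns of equal richness
  set.seed(3)
  for (rep in 1:20) {
    k <- sample(2:10, 1)
    p <- rgamma(k, 1)
    p <- p / sum(p)
    expect_lte(shannon_diversity(p), log(k) + 1e-12)
  }
})

test_that("richness counts present taxa", {
  expect_equal(richness(c(2, 3, 5)), 3)
  expect_equal(richness(c(0, 0, 0)), 0)
  expect_equal(richness(c(0, 0, 7)), 1)
})

test_that("ubiquity is the fraction of contexts occupied and is monotone", {
  m <- matrix(c(1, 0, 2, 0, 3, 0), 2, dimnames = list(c("a", "b"), NULL))
  colnames(m) <- c("X", "Y", "Z")
  mni <- mni_from_matrix(m)
  expect_equal(ubiquity(mni, "a"), 1)
  expect_equal(ubiquity(mni, "b"), 0)
  expect_error(ubiquity(mni, "zzz"), "Unknown taxon")
  # adding an occurrence never decreases ubiquity
  set.seed(5)
  for (rep in 1:10) {
    m <- matrix(rbinom(12, 1, 0.4) * rpois(12, 2), 3,
                dimnames = list(c("a", "b", "c"), sprintf("c%d", 1:4)))
    before <- ubiquity(mni_from_matrix(m), "b")
    cell <- sample(4, 1)
    m["b", cell] <- m["b", cell] + 1L
    expect_gte(ubiquity(mni_from_matrix(m), "b"), before)
  }
  # mullet occurs in every Pineland context
  expect_equal(ubiquity(pineland_mni(), "Mugil spp."), 1)
})

test_that("exclusive-habitat filter keeps single-habitat invertebrates only", {
  mni <- mni_from_matrix(matrix(1, 4, 2, dimnames = list(
    c("one", "two", "none", "vert"), c("X", "Y"))))
  taxa <- taxa_meta(c("one", "two", "none", "vert"),
                    class = c("invertebrate", "invertebrate", "invertebrate",
                              "vertebrate"),
                    habitats = list("oyster_bed",
                                    c("oyster_bed", "seagrass_meadow"),
                                    character(), "littoral"))
  out <- filter_exclusive_habitat(mni, taxa)
  expect_equal(out$taxon_id, "one")
  expect_equal(names(out), names(mni))
})

test_that("habitat collapse conserves mass and honours its scope", {
  mni <- mni_from_matrix(matrix(c(10, 30), 2,
                                dimnames = list(c("a", "b"), "X")))
  taxa <- taxa_meta(c("a", "b"),
                    habitats = list("oyster_bed", "seagrass_meadow"))
  hp <- collapse_to_habitats(mni, taxa)
  expect_equal(hp$X[hp$habitat == "oyster_bed"], 0.25)
  expect_equal(hp$X[hp$habitat == "seagrass_meadow"], 0.75)
  expect_equal(sum(hp$X), 1)

  # a context with taxa from a single habitat gives that habitat share 1
  taxa1 <- taxa_meta(c("a", "b"), habitats = list("tidal_stream", "tidal_stream"))
  hp1 <- collapse_to_habitats(mni, taxa1)
  expect_equal(hp1$X[hp1$habitat == "tidal_stream"], 1)
  expect_equal(sum(hp1$X), 1)

  # fractional scope splits multi-habitat taxa equally and still sums to 1
  taxa2 <- taxa_meta(c("a", "b"),
                     habitats = list(c("oyster_bed", "littoral"),
                                     "seagrass_meadow"))
  hp2 <- collapse_to_habitats(mni, taxa2, scope = "fractional")
  expect_equal(hp2$X[hp2$habitat == "oyster_bed"], 0.125)
  expect_equal(hp2$X[hp2$habitat == "littoral"], 0.125)
  expect_equal(sum(hp2$X), 1)
  # under the default exclusive scope the multi-habitat taxon is dropped
  hp3 <- collapse_to_habitats(mni, taxa2)
  expect_equal(hp3$X[hp3$habitat == "seagrass_meadow"], 1)

  # context with zero classified MNI is flagged
  mni0 <- mni_from_matrix(matrix(c(10, 30, 0, 0), 2,
                                 dimnames = list(c("a", "b"), c("X", "Y"))))
  expect_warning(hp0 <- collapse_to_habitats(mni0, taxa), "flagged")
  expect_true(all(is.na(hp0$Y)))
})

test_that("context metrics table combines totals, richness and diversity", {
  mni <- mni_from_matrix(matrix(c(2, 3, 5, 0, 0, 0), 3,
                                dimnames = list(c("a", "b", "c"), c("X", "Y"))))
  cm <- context_metrics(mni)
  expect_equal(cm$total_mni, c(10L, 0L))
  expect_equal(cm$richness, c(3L, 0L))
  expect_equal(cm$shannon[1], shannon_diversity(c(0.2, 0.3, 0.5)))
  expect_true(is.na(cm$shannon[2]))
})
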