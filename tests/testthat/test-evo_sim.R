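test_that("parameters are validated", {
  expect_error(sim_params(rate_loss_mirna = -1), "negative")
  expect_error(sim_params(rho = 1.5), "rho")
  expect_error(sim_params(birth_offset = c(50, 20000)), "birth_offset")
})

test_that("with all rates zero every species keeps the root repertoire", {
  phy <- fixture_tree()
  p <- sim_params(rate_new_hairpin_in_transcript = 0,
                  rate_intergenic_birth = 0, rate_tandem_duplication = 0,
                  rate_loss_mirna = 0, rate_loss_cluster = 0,
                  rate_translocation = 0, seed = 3)
  sim <- simulate_mirna_evolution(phy, p)
  expect_equal(nrow(sim$event_log), 0)
  for (sp in names(sim$species)) {
    l <- sim$species[[sp]]
    # identity up to neutral coordinate drift: ids, families, placement class
    expect_setequal(l$mirna_id, sim$root_loci$id)
    expect_equal(l$phylo_family[match(sim$root_loci$id, l$mirna_id)],
                 sim$root_loci$family)
    expect_equal(l$chrom[match(sim$root_loci$id, l$mirna_id)],
                 sim$root_loci$chrom)
    expect_equal(nrow(call_clusters(l, p$max_gap)), 0)  # root loci unclustered
  }
})

test_that("a fixed seed gives identical runs and byte-identical outputs", {
  phy <- fixture_tree()
  p <- sim_params(seed = 11)
  s1 <- simulate_mirna_evolution(phy, p)
  s2 <- simulate_mirna_evolution(phy, p)
  expect_identical(s1$species, s2$species)
  expect_identical(s1$event_log, s2$event_log)
  d1 <- tempfile()
  d2 <- tempfile()
  dir.create(d1)
  dir.create(d2)
  for (sp in names(s1$species)) {
    write_mirna_gff3(s1$species[[sp]], file.path(d1, paste0(sp, ".gff3")))
    write_mirna_gff3(s2$species[[sp]], file.path(d2, paste0(sp, ".gff3")))
    expect_identical(readBin(file.path(d1, paste0(sp, ".gff3")), "raw", 1e6),
                     readBin(file.path(d2, paste0(sp, ".gff3")), "raw", 1e6))
  }
})

test_that("replaying the event log reproduces the extant genomes exactly", {
  phy <- fixture_tree()
  for (seed in c(2, 19, 101)) {
    p <- sim_params(seed = seed, rate_translocation = 0.02)
    sim <- simulate_mirna_evolution(phy, p)
    rp <- replay_event_log(phy, p, sim$event_log)
    expect_identical(sim$species, rp$species, info = paste("seed", seed))
  }
})

test_that("single-process regimes produce only their own event type", {
  phy <- fixture_tree()
  p_dup <- sim_params(rate_new_hairpin_in_transcript = 0,
                      rate_intergenic_birth = 0, rate_loss_mirna = 0,
                      rate_loss_cluster = 0, rate_translocation = 0,
                      seed = 7)
  sim <- simulate_mirna_evolution(phy, p_dup)
  expect_true(all(sim$event_log$event == "duplication"))
  # every cluster in every species traces back to duplication only
  for (sp in names(sim$species)) {
    cl <- call_clusters(sim$species[[sp]], p_dup$max_gap)
    for (m in cl$members) {
      fams <- sim$species[[sp]]$phylo_family[
        match(m, sim$species[[sp]]$mirna_id)]
      expect_length(unique(fams), 1)  # tandem copies share the family
    }
  }
  p_nh <- sim_params(rate_intergenic_birth = 0, rate_tandem_duplication = 0,
                     rate_loss_mirna = 0, rate_loss_cluster = 0,
                     rate_translocation = 0, seed = 7)
  sim2 <- simulate_mirna_evolution(phy, p_nh)
  expect_true(all(sim2$event_log$event == "birth_in_transcript"))
})

test_that("new hairpins are born clustered with their parent, with a new family", {
  phy <- fixture_tree()
  p <- sim_params(seed = 23)
  sim <- simulate_mirna_evolution(phy, p)
  log <- sim$event_log
  births <- log[log$event == "birth_in_transcript", , drop = FALSE]
  expect_gt(nrow(births), 0)
  # a birth founds a new family, distinct from every root family
  expect_false(any(births$family %in% sim$root_loci$family))
  dups <- log[log$event == "duplication", , drop = FALSE]
  if (nrow(dups) > 0) {
    creators <- rbind(births, dups)
    fam_of <- setNames(c(sim$root_loci$family, creators$family),
                       c(sim$root_loci$id, creators$locus))
    expect_equal(unname(fam_of[dups$parent]), dups$family)
  }
  # wherever child and parent are both extant they share a cluster
  for (sp in names(sim$species)) {
    l <- sim$species[[sp]]
    asg <- attr(call_clusters(l, p$max_gap), "assignment")
    both <- births[births$locus %in% l$mirna_id &
                     births$parent %in% l$mirna_id, , drop = FALSE]
    if (nrow(both) > 0) {
      expect_true(all(!is.na(asg[both$locus])))
      expect_equal(unname(asg[both$locus]), unname(asg[both$parent]))
    }
  }
})

test_that("expression generator respects rho limits and count support", {
  start <- as.integer(seq(1, by = 50000, length.out = 200))
  start <- as.vector(rbind(start, start + 300L))  # 200 clusters of 2
  loci <- loci_tbl(start = start, end = start + 99L,
                   id = sprintf("mir-e%03d", seq_along(start)))
  cl <- call_clusters(loci, 10000)
  expect_equal(nrow(cl), 200)
  within_r <- function(m) {
    vapply(cl$members, function(mem)
      pearson_counts(m[mem[1], ], m[mem[2], ]), 0)
  }
  m1 <- generate_expression(loci, cl, rho = 1, n_samples = 30, seed = 8,
                            dispersion = 0)
  expect_true(all(m1 >= 0) && all(m1 == round(m1)))
  expect_gt(median(within_r(m1)), 0.95)  # rho = 1, vanishing dispersion
  m0 <- generate_expression(loci, cl, rho = 0, n_samples = 30, seed = 8)
  expect_lt(abs(mean(within_r(m0), na.rm = TRUE)), 0.05)  # rho = 0
  expect_error(generate_expression(loci, cl, rho = 2), "rho")
})

test_that("older microRNAs are clustered more often when clusters are protected", {
  phy <- fixture_tree()
  # singletons are born mostly intergenic and die fast; clusters persist
  p <- sim_params(rate_new_hairpin_in_transcript = 0.06,
                  rate_intergenic_birth = 8, rate_tandem_duplication = 0.02,
                  rate_loss_mirna = 1.5, rate_loss_cluster = 0.05,
                  rate_translocation = 0, n_root_loci = 15)
  old_lin <- c("Metazoans", "Protostomes", "Insects", "Diptera")
  young_lin <- c("Drosophila", "SimPse", "Melanogaster")
  tot <- c(old = 0, young = 0)
  clu <- c(old = 0, young = 0)
  for (seed in 1:6) {
    p$seed <- 1000L + seed
    sim <- simulate_mirna_evolution(phy, p)
    l <- sim$species$dme
    present_in <- function(id) names(Filter(function(x)
      id %in% x$mirna_id, sim$species))
    ages <- vapply(l$mirna_id, function(id)
      as.character(infer_origin_node(present_in(id), phy)), "")
    out <- clustered_fraction_by_age(l, ages, max_gap = p$max_gap)
    is_old <- out$lineage %in% old_lin
    tot["old"] <- tot["old"] + sum(out$n_loci[is_old])
    clu["old"] <- clu["old"] + sum(out$n_clustered[is_old])
    is_young <- out$lineage %in% young_lin
    tot["young"] <- tot["young"] + sum(out$n_loci[is_young])
    clu["young"] <- clu["young"] + sum(out$n_clustered[is_young])
  }
  expect_gt(clu[["old"]] / tot[["old"]], clu[["young"]] / tot[["young"]])
})

test_that("exact homology can be degraded with a false-negative rate", {
  phy <- fixture_tree()
  sim <- simulate_mirna_evolution(phy, sim_params(seed = 4))
  h0 <- sim_homology(sim)
  h1 <- sim_homology(sim, fn_rate = 0.3, focal = "dme", seed = 2)
  expect_lt(nrow(h1$loci), nrow(h0$loci))
  expect_equal(nrow(hl <- h1$loci[h1$loci$species_id == "dme", ]),
               nrow(sim$species$dme))  # focal species never degraded
})
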