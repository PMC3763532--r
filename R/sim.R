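#' Parameters for the microRNA repertoire simulator
#'
#' All event rates are per unit branch length (branch lengths are in
#' arbitrary time units): `rate_new_hairpin_in_transcript` per existing
#' transcript (a transcript is a cluster or a singleton locus),
#' `rate_intergenic_birth` per genome, `rate_tandem_duplication` and
#' `rate_translocation` per locus, `rate_loss_mirna` per \emph{singleton}
#' locus, `rate_loss_cluster` per cluster (clusters gain and lose members
#' through their own events but are lost as whole units, which is the
#' empirically dominant mode for microRNA clusters).
#'
#' @param rate_new_hairpin_in_transcript De novo hairpin birth inside an
#'   existing microRNA transcript; founds a new family next to its parent.
#' @param rate_intergenic_birth De novo hairpin birth at a random genomic
#'   position (new family, usually a singleton).
#' @param rate_tandem_duplication Local copy of a locus, same family.
#' @param rate_loss_mirna Loss of a singleton microRNA.
#' @param rate_loss_cluster Loss of a whole cluster.
#' @param rate_translocation Move of a locus to a random distant position.
#' @param tandem_offset Range (nt) of the gap between a tandem copy and its
#'   template.
#' @param birth_offset Range (nt) of the gap between a new hairpin and its
#'   parent locus; must stay below `max_gap` so the child is born clustered.
#' @param n_root_loci Size of the seed repertoire at the root (placed well
#'   separated, so the root repertoire contains no clusters).
#' @param n_chromosomes,chrom_length Genome layout.
#' @param max_gap Clustering threshold used inside the simulator.
#' @param rho Within-cluster expression correlation for
#'   [generate_expression()].
#' @param seed Integer seed; all per-branch random streams are derived from
#'   it, so a fixed seed gives byte-identical output.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(rate_new_hairpin_in_transcript = 0.15,
                       rate_intergenic_birth = 0.05,
                       rate_tandem_duplication = 0.08,
                       rate_loss_mirna = 0.05,
                       rate_loss_cluster = 0.01,
                       rate_translocation = 0,
                       tandem_offset = c(50, 500),
                       birth_offset = c(50, 2000),
                       n_root_loci = 25,
                       n_chromosomes = 4,
                       chrom_length = 2e7,
                       max_gap = 10000,
                       rho = 0.9,
                       seed = 1) {
  p <- list(rate_new_hairpin_in_transcript = rate_new_hairpin_in_transcript,
            rate_intergenic_birth = rate_intergenic_birth,
            rate_tandem_duplication = rate_tandem_duplication,
            rate_loss_mirna = rate_loss_mirna,
            rate_loss_cluster = rate_loss_cluster,
            rate_translocation = rate_translocation,
            tandem_offset = tandem_offset, birth_offset = birth_offset,
            n_root_loci = n_root_loci, n_chromosomes = n_chromosomes,
            chrom_length = chrom_length, max_gap = max_gap, rho = rho,
            seed = as.integer(seed))
  rates <- unlist(p[grep("^rate_", names(p))])
  if (any(rates < 0)) stop("negative rates are not allowed")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (birth_offset[2] >= max_gap)
    stop("birth_offset must stay below max_gap")
  class(p) <- "sim_params"
  p
}

# deterministic per-(branch, purpose) seed; kept below 2^31
derive_seed <- function(seed, branch, purpose) {
  ((abs(seed) %% 100000) * 20011 + branch * 2011 + purpose * 7) %% 2147483647
}

# chain group id per locus (running-max single linkage), per chrom+strand
chain_groups <- function(state, max_gap) {
  groups <- integer(nrow(state))
  g <- 0L
  for (key in unique(paste(state$chrom, state$strand))) {
    idx <- which(paste(state$chrom, state$strand) == key)
    idx <- idx[order(state$start[idx], state$end[idx], state$id[idx])]
    g <- g + 1L
    groups[idx[1]] <- g
    right <- state$end[idx[1]]
    for (i in seq_along(idx)[-1]) {
      if (max(0, state$start[idx[i]] - right - 1) >= max_gap) g <- g + 1L
      groups[idx[i]] <- g
      right <- max(right, state$end[idx[i]])
    }
  }
  groups
}

# place [start, start+len-1] avoiding overlap with existing loci on chrom
resolve_overlap <- function(state, chrom, start, len, chrom_length) {
  repeat {
    end <- start + len - 1L
    hit <- which(state$chrom == chrom & state$start <= end & state$end >= start)
    if (length(hit) == 0) break
    start <- max(state$end[hit]) + 51L
  }
  start <- max(1L, min(as.integer(start), as.integer(chrom_length - len)))
  c(start, start + len - 1L)
}

new_state_row <- function(id, chrom, start, end, strand, family) {
  data.frame(id = id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, family = family,
             stringsAsFactors = FALSE)
}

log_row <- function(branch, time, gtime, event, locus, parent, chrom = NA,
                    start = NA, end = NA, strand = NA, family = NA) {
  data.frame(branch = branch, time = time, gtime = gtime, event = event,
             locus = locus, parent = ifelse(is.null(parent), NA, parent),
             chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = as.character(strand), family = as.character(family),
             stringsAsFactors = FALSE)
}

sim_root_state <- function(p) {
  set.seed(derive_seed(p$seed, 0L, 0L))
  rows <- vector("list", p$n_root_loci)
  per_chrom <- integer(p$n_chromosomes)
  for (k in seq_len(p$n_root_loci)) {
    ch <- (k - 1L) %% p$n_chromosomes + 1L
    per_chrom[ch] <- per_chrom[ch] + 1L
    len <- sample(60:120, 1)
    # >= 5 * max_gap apart: the seed repertoire holds no clusters
    start <- per_chrom[ch] * 10L * p$max_gap +
      as.integer(floor(stats::runif(1, 0, 4 * p$max_gap)))
    rows[[k]] <- new_state_row(sprintf("Lroot_%03d", k), paste0("chr", ch),
                               start, start + len - 1L,
                               sample(c("+", "-"), 1), sprintf("Froot_%03d", k))
  }
  do.call(rbind, rows)
}

# Gillespie event sampling along one branch
sim_branch <- function(state, branch_label, branch_idx, len, t0, p) {
  set.seed(derive_seed(p$seed, branch_idx, 1L))
  logs <- list()
  nh_n <- 0L
  t <- 0
  repeat {
    groups <- chain_groups(state, p$max_gap)
    sizes <- table(groups)
    cluster_ids <- as.integer(names(sizes)[sizes >= 2])
    singleton_rows <- which(groups %in% as.integer(names(sizes)[sizes == 1]))
    n_loci <- nrow(state)
    n_clusters <- length(cluster_ids)
    n_transcripts <- n_clusters + length(singleton_rows)
    rates <- c(
      birth_in_transcript = p$rate_new_hairpin_in_transcript * n_transcripts,
      birth_intergenic = p$rate_intergenic_birth,
      duplication = p$rate_tandem_duplication * n_loci,
      loss = p$rate_loss_mirna * length(singleton_rows),
      cluster_loss = p$rate_loss_cluster * n_clusters,
      translocation = p$rate_translocation * n_loci
    )
    total <- sum(rates)
    if (total <= 0) break
    t <- t + stats::rexp(1, total)
    if (t > len) break
    ev <- sample(names(rates), 1, prob = rates)
    nh_n <- nh_n + 1L
    if (ev == "birth_in_transcript" || ev == "duplication") {
      if (ev == "birth_in_transcript") {
        tg <- sample(unique(groups), 1)
        parent <- sample(rep(which(groups == tg), 2), 1)
        offs <- p$birth_offset
        fam <- sprintf("F%s_%03d", branch_label, nh_n)
      } else {
        parent <- sample(rep(seq_len(n_loci), 2), 1)
        offs <- p$tandem_offset
        fam <- state$family[parent]
      }
      newlen <- sample(60:120, 1)
      off <- as.integer(floor(stats::runif(1, offs[1], offs[2] + 1)))
      start0 <- if (stats::runif(1) < 0.5) state$end[parent] + off + 1L else
        state$start[parent] - off - newlen
      se <- resolve_overlap(state, state$chrom[parent], start0, newlen,
                            p$chrom_length)
      id <- sprintf("L%s_%03d", branch_label, nh_n)
      row <- new_state_row(id, state$chrom[parent], se[1], se[2],
                           state$strand[parent], fam)
      state <- rbind(state, row)
      logs[[length(logs) + 1]] <- log_row(branch_label, t, t0 + t, ev, id,
                                          state$id[parent], row$chrom,
                                          row$start, row$end, row$strand, fam)
    } else if (ev == "birth_intergenic") {
      newlen <- sample(60:120, 1)
      ch <- paste0("chr", sample(p$n_chromosomes, 1))
      se <- resolve_overlap(state, ch,
                            as.integer(floor(stats::runif(1, 1, p$chrom_length - newlen))),
                            newlen, p$chrom_length)
      id <- sprintf("L%s_%03d", branch_label, nh_n)
      fam <- sprintf("F%s_%03d", branch_label, nh_n)
      row <- new_state_row(id, ch, se[1], se[2], sample(c("+", "-"), 1), fam)
      state <- rbind(state, row)
      logs[[length(logs) + 1]] <- log_row(branch_label, t, t0 + t, ev, id, NA,
                                          row$chrom, row$start, row$end,
                                          row$strand, fam)
    } else if (ev == "loss") {
      victim <- sample(rep(singleton_rows, 2), 1)
      logs[[length(logs) + 1]] <- log_row(branch_label, t, t0 + t, ev,
                                          state$id[victim], NA)
      state <- state[-victim, , drop = FALSE]
    } else if (ev == "cluster_loss") {
      cg <- sample(rep(cluster_ids, 2), 1)
      victims <- which(groups == cg)
      logs[[length(logs) + 1]] <- log_row(branch_label, t, t0 + t, ev,
                                          paste(state$id[victims], collapse = ","),
                                          NA)
      state <- state[-victims, , drop = FALSE]
    } else { # translocation
      victim <- sample(rep(seq_len(n_loci), 2), 1)
      newlen <- state$end[victim] - state$start[victim] + 1L
      ch <- paste0("chr", sample(p$n_chromosomes, 1))
      se <- resolve_overlap(state[-victim, , drop = FALSE], ch,
                            as.integer(floor(stats::runif(1, 1, p$chrom_length - newlen))),
                            newlen, p$chrom_length)
      state$chrom[victim] <- ch
      state$start[victim] <- se[1]
      state$end[victim] <- se[2]
      logs[[length(logs) + 1]] <- log_row(branch_label, t, t0 + t, ev,
                                          state$id[victim], NA, ch, se[1],
                                          se[2], state$strand[victim],
                                          state$family[victim])
    }
    rownames(state) <- NULL
  }
  list(state = state,
       log = if (length(logs)) do.call(rbind, logs) else NULL)
}

# neutral coordinate drift at the end of a branch: inter-locus gaps are
# jittered multiplicatively but clamped on their side of max_gap, so the
# linkage classes (clustered vs not) are preserved exactly
drift_coords <- function(state, seed_val, max_gap) {
  set.seed(seed_val)
  for (key in unique(paste(state$chrom, state$strand))) {
    idx <- which(paste(state$chrom, state$strand) == key)
    idx <- idx[order(state$start[idx], state$end[idx], state$id[idx])]
    lens <- state$end[idx] - state$start[idx] + 1L
    gaps <- if (length(idx) > 1)
      state$start[idx][-1] - state$end[idx][-length(idx)] - 1L else integer()
    shift <- as.integer(round(stats::rnorm(1, 0, 300)))
    s <- max(1L, state$start[idx[1]] + shift)
    for (i in seq_along(idx)) {
      if (i > 1) {
        gap <- gaps[i - 1]
        g2 <- as.integer(round(gap * stats::runif(1, 0.85, 1.18)))
        g2 <- if (gap < max_gap) max(0L, min(max_gap - 1L, g2)) else
          max(max_gap, g2)
        s <- s + g2
      }
      state$start[idx[i]] <- s
      state$end[idx[i]] <- s + lens[i] - 1L
      s <- s + lens[i]
    }
  }
  state
}

#' Simulate microRNA repertoires evolving along a species tree
#'
#' Gillespie-style birth-death simulation of microRNA loci along each branch
#' of a species tree, under six event types: de novo hairpin birth inside an
#' existing transcript (founds a cluster; new family), intergenic de novo
#' birth (new family), tandem duplication (same family, adjacent copy), loss
#' of a singleton microRNA, loss of a whole cluster, and translocation to a
#' random distant position. Between speciations, coordinates drift neutrally
#' while linkage (clustered vs not) is preserved. Random streams are keyed
#' by `(seed, branch)`, so results are reproducible and branch-local.
#'
#' @param tree A `species_phylogeny` with branch lengths.
#' @param params A [sim_params()] object.
#' @return An object of class `mirna_sim`: list with `species` (named list
#'   of `mirna_loci`; `mirna_id` is the locus id, shared across species by
#'   descent and used as `ortholog_group`), `event_log` (data.frame),
#'   `root_loci`, `tree`, `params`.
#' @export
simulate_mirna_evolution <- function(tree, params = sim_params()) {
  if (!inherits(tree, "species_phylogeny")) stop("tree must be a species_phylogeny")
  if (is.null(tree$tree$edge.length)) stop("tree must have branch lengths")
  if (!inherits(params, "sim_params")) stop("params must come from sim_params()")
  run_over_tree(tree, params, replay_log = NULL)
}

#' Replay an event log over the tree
#'
#' Rebuilds the extant genomes by replaying a ground-truth [EventLog]
#' deterministically: events are applied from their recorded coordinates and
#' the per-branch coordinate-drift streams are re-derived from the seed.
#' Replaying the log of [simulate_mirna_evolution()] with the same
#' parameters reproduces its extant genomes exactly.
#'
#' @param tree A `species_phylogeny` with branch lengths.
#' @param params The same [sim_params()] used for the original run.
#' @param event_log The `event_log` of a `mirna_sim`.
#' @return A `mirna_sim` (with the same `event_log`).
#' @export
replay_event_log <- function(tree, params, event_log) {
  run_over_tree(tree, params, replay_log = event_log)
}

replay_branch <- function(state, branch_label, rows) {
  if (!is.null(rows) && nrow(rows) > 0) {
    rows <- rows[order(rows$time), , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      if (r$event %in% c("birth_in_transcript", "birth_intergenic",
                         "duplication")) {
        state <- rbind(state, new_state_row(r$locus, r$chrom, r$start, r$end,
                                            r$strand, r$family))
      } else if (r$event %in% c("loss", "cluster_loss")) {
        ids <- strsplit(r$locus, ",", fixed = TRUE)[[1]]
        state <- state[!(state$id %in% ids), , drop = FALSE]
      } else { # translocation
        j <- match(r$locus, state$id)
        state$chrom[j] <- r$chrom
        state$start[j] <- r$start
        state$end[j] <- r$end
      }
    }
    rownames(state) <- NULL
  }
  state
}

run_over_tree <- function(tree, params, replay_log = NULL) {
  tr <- tree$tree
  ntip <- length(tr$tip.label)
  root_state <- sim_root_state(params)
  states <- vector("list", ntip + tr$Nnode)
  states[[ntip + 1L]] <- root_state
  node_times <- phy_node_times(tree)
  logs <- list()
  e <- tr$edge
  labels <- c(tr$tip.label, tr$node.label)
  for (i in seq_len(nrow(e))) {  # cladewise: parents before children
    parent <- e[i, 1]
    child <- e[i, 2]
    blabel <- labels[child]
    if (is.null(replay_log)) {
      res <- sim_branch(states[[parent]], blabel, child, tr$edge.length[i],
                        node_times[parent], params)
      st <- res$state
      if (!is.null(res$log)) logs[[length(logs) + 1]] <- res$log
    } else {
      rows <- replay_log[replay_log$branch == blabel, , drop = FALSE]
      st <- replay_branch(states[[parent]], blabel, rows)
    }
    st <- drift_coords(st, derive_seed(params$seed, child, 2L), params$max_gap)
    states[[child]] <- st
  }
  species <- lapply(seq_len(ntip), function(i) {
    st <- states[[i]]
    mirna_loci(mirna_id = st$id, species_id = tr$tip.label[i],
               chrom = st$chrom, start = st$start, end = st$end,
               strand = st$strand, annotation_family = st$family,
               phylo_family = st$family, ortholog_group = st$id)
  })
  names(species) <- tr$tip.label
  event_log <- if (is.null(replay_log)) {
    if (length(logs)) do.call(rbind, logs) else
      log_row("", 0, 0, "", "", NA)[0, ]
  } else replay_log
  rownames(event_log) <- NULL
  out <- list(species = species, event_log = event_log,
              root_loci = root_state, tree = tree, params = params)
  class(out) <- "mirna_sim"
  out
}

#' @export
print.mirna_sim <- function(x, ...) {
  cat("mirna_sim:", length(x$species), "species;",
      nrow(x$event_log), "events; root repertoire",
      nrow(x$root_loci), "loci\n")
  invisible(x)
}

#' Homology map of a simulation
#'
#' Homology in the simulator is exact: orthologs share the locus id across
#' species (`ortholog_group`), paralogs share the family. An optional
#' per-species false-negative rate drops each non-focal homolog entry
#' independently, emulating homology-detection misses.
#'
#' @param sim A `mirna_sim`.
#' @param fn_rate Per-locus probability that a homolog in a non-focal
#'   species is missed (default 0 = exact).
#' @param focal Species whose entries are never dropped.
#' @param seed Seed for the detection-noise draws.
#' @return A `homology_map` over all simulated species.
#' @export
sim_homology <- function(sim, fn_rate = 0, focal = NULL, seed = 1) {
  loci <- do.call(rbind, sim$species)
  rownames(loci) <- NULL
  if (fn_rate > 0) {
    set.seed(seed)
    drop <- stats::runif(nrow(loci)) < fn_rate & loci$species_id != focal
    loci <- loci[!drop, , drop = FALSE]
  }
  homology_map(loci, species = names(sim$species))
}

#' Generate a synthetic expression matrix with within-cluster correlation
#'
#' Each cluster draws a latent log-normal per-sample profile; a member's
#' expected count is the mixture `rho * cluster profile + (1 - rho) * own
#' independent profile`, and observed counts are negative-binomial draws
#' around it (Poisson when `dispersion = 0`). Singletons use only their own
#' profile. With `rho = 1` and vanishing dispersion, within-cluster pairwise
#' Pearson correlations approach 1; with `rho = 0`, members are independent.
#'
#' @param loci A `mirna_loci` table.
#' @param clusters Output of [call_clusters()] on `loci` (its member
#'   assignment defines the latent profile sharing).
#' @param rho Within-cluster correlation weight in `[0, 1]`.
#' @param n_samples Number of samples (tissues/stages).
#' @param seed Integer seed.
#' @param base_mean Median expected count.
#' @param profile_sd Log-scale standard deviation of latent profiles.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @return Integer count matrix, rows = mirna_id, columns = samples.
#' @export
generate_expression <- function(loci, clusters, rho, n_samples = 20, seed = 1,
                                base_mean = 500, profile_sd = 1.5,
                                dispersion = 0.1) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  set.seed(seed)
  assign <- attr(clusters, "assignment")
  if (is.null(assign))
    stop("clusters must carry a member assignment (use call_clusters)")
  unit <- assign[loci$mirna_id]
  unit[is.na(unit)] <- paste0("singleton_", loci$mirna_id[is.na(unit)])
  lmean <- log(base_mean) - profile_sd^2 / 2
  latent <- lapply(unique(unit), function(u)
    exp(stats::rnorm(n_samples, lmean, profile_sd)))
  names(latent) <- unique(unit)
  m <- matrix(0L, nrow = nrow(loci), ncol = n_samples,
              dimnames = list(loci$mirna_id,
                              sprintf("sample_%02d", seq_len(n_samples))))
  for (i in seq_len(nrow(loci))) {
    own <- exp(stats::rnorm(n_samples, lmean, profile_sd))
    shared <- if (startsWith(unit[i], "singleton_")) 0 else rho
    mu <- shared * latent[[unit[i]]] + (1 - shared) * own
    m[i, ] <- if (dispersion > 0)
      stats::rnbinom(n_samples, mu = mu, size = 1 / dispersion) else
        stats::rpois(n_samples, mu)
  }
  m
}

# creation record (type, global time, parent) per locus id
creation_table <- function(sim) {
  log <- sim$event_log
  born <- log[log$event %in% c("birth_in_transcript", "birth_intergenic",
                               "duplication"), , drop = FALSE]
  ct <- data.frame(id = c(sim$root_loci$id, born$locus),
                   type = c(rep("root", nrow(sim$root_loci)), born$event),
                   gtime = c(rep(-1, nrow(sim$root_loci)), born$gtime),
                   stringsAsFactors = FALSE)
  ct[!duplicated(ct$id), , drop = FALSE]
}

# ground-truth founding event of an extant cluster: the creation event of
# the second-oldest extant member (the event that made the group a cluster)
true_founding_event <- function(members, creation, trans_log) {
  rows <- creation[match(members, creation$id), , drop = FALSE]
  rows <- rows[order(rows$gtime), , drop = FALSE]
  second <- rows[2, ]
  if (nrow(trans_log) > 0 &&
      any(trans_log$locus %in% rows$id[1:2] & trans_log$gtime > second$gtime))
    return("FUSION")
  switch(second$type,
         duplication = "DUPLICATION",
         birth_in_transcript = "NEW_HAIRPIN",
         birth_intergenic = "NEW_HAIRPIN",
         root = "ANCESTRAL")
}

#' Founding-event recovery experiment
#'
#' End-to-end validation of the origin classifier against simulated ground
#' truth: for each replicate, simulate repertoires, call clusters in the
#' focal species, build the (exact) homology map, classify every cluster's
#' founding event, and compare with the event log's true founding event (the
#' creation event of the cluster's second-oldest extant member). Reports the
#' confusion matrix and per-class precision/recall.
#'
#' @param tree A `species_phylogeny` with branch lengths.
#' @param params A [sim_params()]; its seed is overridden per replicate.
#' @param n_reps Number of replicates.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param focal Focal species (default: first leaf).
#' @return A list with `confusion` (truth x call table), `per_class`
#'   (data.frame: class, n_true, recall, precision), `calls` (all calls with
#'   truth attached) and `n_clusters`.
#' @export
recovery_experiment <- function(tree, params, n_reps, seed = 1, focal = NULL) {
  if (is.null(focal)) focal <- tree$tree$tip.label[1]
  all <- list()
  for (r in seq_len(n_reps)) {
    p <- params
    p$seed <- (seed + r) %% 2147483647L
    sim <- simulate_mirna_evolution(tree, p)
    clusters <- call_clusters(sim$species[[focal]], max_gap = p$max_gap)
    if (nrow(clusters) == 0) next
    hom <- sim_homology(sim)
    calls <- classify_clusters(clusters, hom, tree, max_gap = p$max_gap)
    creation <- creation_table(sim)
    trans <- sim$event_log[sim$event_log$event == "translocation", ,
                           drop = FALSE]
    calls$truth <- vapply(clusters$members, function(m)
      true_founding_event(m, creation, trans), "")
    calls$rep <- r
    all[[length(all) + 1]] <- calls
  }
  calls <- do.call(rbind, all)
  lev <- union(SOURCE_LEVELS, "ANCESTRAL")
  confusion <- table(truth = factor(calls$truth, levels = lev),
                     call = factor(calls$source, levels = lev))
  classes <- setdiff(unique(calls$truth), "ANCESTRAL")
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(calls$truth == cl & calls$source == cl)
    data.frame(class = cl, n_true = sum(calls$truth == cl),
               recall = tp / sum(calls$truth == cl),
               precision = if (sum(calls$source == cl) > 0)
                 tp / sum(calls$source == cl) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(confusion = confusion, per_class = per_class, calls = calls,
       n_clusters = nrow(calls))
}
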