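#' Community succession scenario
#'
#' Parameters of the synthetic 16S survey: a genus pool with target
#' relative-abundance trajectories over the sampling time points, read
#' depth, Dirichlet-multinomial overdispersion, and the number of ASVs per
#' genus. The default trajectory emulates the observed succession — an even
#' early community led by *Pseudomonas*, a shift to *Brevundimonas*
#' dominance with *Pseudomonas* and *Duganella* vanishing by the middle time
#' point, then further dominance with rising *Porphyrobacter* and the loss
#' of *Terrimonas* and *Ensifer* — with genus-level Shannon diversity
#' declining 2.14 -> 1.41 -> 0.86.
#'
#' @param time_points sampling time-point labels.
#' @param n_replicates samples per time point.
#' @param trajectories genus x time-point matrix of target relative
#'   abundances (columns sum to 1).
#' @param total_reads reads per sample.
#' @param concentration Dirichlet-multinomial concentration; larger values
#'   give tighter replicates.
#' @param asvs_per_genus ASVs carried by each genus.
#' @param within_genus_split fixed profile splitting a genus's abundance
#'   over its ASVs (normalized to sum to 1; shared by all genera so the
#'   ASV-level diversity is a stable offset of the genus-level diversity).
#' @param seed RNG seed.
#' @return object of class `ces_community_scenario`.
#' @export
community_scenario <- function(time_points = c("day8", "day33", "day54"),
                               n_replicates = 2,
                               trajectories = NULL,
                               total_reads = 50000,
                               concentration = 1000,
                               asvs_per_genus = 3,
                               within_genus_split = c(0.8, 0.1, 0.1),
                               seed = 1) {
  if (is.null(trajectories)) {
    trajectories <- default_genus_trajectories()[, seq_along(time_points), drop = FALSE]
  }
  if (ncol(trajectories) != length(time_points)) {
    stopf("need one trajectory column per time point")
  }
  if (any(trajectories < 0) || any(abs(colSums(trajectories) - 1) > 1e-8)) {
    stopf("trajectories must be probability vectors per time point")
  }
  if (total_reads < 1) stopf("total_reads must be >= 1")
  if (length(within_genus_split) != asvs_per_genus ||
      any(within_genus_split <= 0)) {
    stopf("within_genus_split must have asvs_per_genus positive entries")
  }
  colnames(trajectories) <- time_points
  structure(
    list(time_points = time_points, n_replicates = n_replicates,
         trajectories = trajectories, total_reads = total_reads,
         concentration = concentration, asvs_per_genus = asvs_per_genus,
         within_genus_split = within_genus_split / sum(within_genus_split),
         seed = seed),
    class = "ces_community_scenario"
  )
}

default_genus_trajectories <- function() {
  m <- rbind(
    Pseudomonas    = c(0.300, 0.00, 0.00),
    Brevundimonas  = c(0.100, 0.60, 0.75),
    Ensifer        = c(0.090, 0.02, 0.00),
    Duganella      = c(0.085, 0.00, 0.00),
    Ferrovibrio    = c(0.080, 0.08, 0.03),
    Porphyrobacter = c(0.075, 0.10, 0.15),
    Terrimonas     = c(0.075, 0.06, 0.00),
    Sphingopyxis   = c(0.070, 0.06, 0.02),
    Blastomonas    = c(0.065, 0.05, 0.01),
    Phreatobacter  = c(0.060, 0.03, 0.04)
  )
  colnames(m) <- c("day8", "day33", "day54")
  m
}

GENUS_LINEAGE <- c(
  Pseudomonas    = "d__Bacteria;p__Pseudomonadota;c__Gammaproteobacteria;o__Pseudomonadales;f__Pseudomonadaceae;g__Pseudomonas;s__",
  Brevundimonas  = "d__Bacteria;p__Pseudomonadota;c__Alphaproteobacteria;o__Caulobacterales;f__Caulobacteraceae;g__Brevundimonas;s__",
  Ensifer        = "d__Bacteria;p__Pseudomonadota;c__Alphaproteobacteria;o__Hyphomicrobiales;f__Rhizobiaceae;g__Ensifer;s__",
  Duganella      = "d__Bacteria;p__Pseudomonadota;c__Gammaproteobacteria;o__Burkholderiales;f__Oxalobacteraceae;g__Duganella;s__",
  Ferrovibrio    = "d__Bacteria;p__Pseudomonadota;c__Alphaproteobacteria;o__Rhodospirillales;f__Ferrovibrionaceae;g__Ferrovibrio;s__",
  Porphyrobacter = "d__Bacteria;p__Pseudomonadota;c__Alphaproteobacteria;o__Sphingomonadales;f__Erythrobacteraceae;g__Porphyrobacter;s__",
  Terrimonas     = "d__Bacteria;p__Bacteroidota;c__Chitinophagia;o__Chitinophagales;f__Chitinophagaceae;g__Terrimonas;s__",
  Sphingopyxis   = "d__Bacteria;p__Pseudomonadota;c__Alphaproteobacteria;o__Sphingomonadales;f__Sphingomonadaceae;g__Sphingopyxis;s__",
  Blastomonas    = "d__Bacteria;p__Pseudomonadota;c__Alphaproteobacteria;o__Sphingomonadales;f__Sphingomonadaceae;g__Blastomonas;s__",
  Phreatobacter  = "d__Bacteria;p__Pseudomonadota;c__Alphaproteobacteria;o__Hyphomicrobiales;f__Phreatobacteraceae;g__Phreatobacter;s__"
)

genus_lineage <- function(genus) {
  known <- GENUS_LINEAGE[genus]
  ifelse(is.na(known),
         sprintf("d__Bacteria;p__unknown;c__unknown;o__unknown;f__unknown;g__%s;s__", genus),
         known)
}

#' Generate a synthetic ASV table
#'
#' ASV counts are Dirichlet-multinomial around the time point's genus
#' trajectory: each genus's abundance is split over its ASVs by a fixed
#' within-genus profile, a per-sample composition is drawn from a Dirichlet
#' centred on those ASV proportions, and reads are drawn multinomially.
#' Taxonomy strings carry the genus in the sixth rank field.
#'
#' @param scenario a [community_scenario()].
#' @return list with `table` (a `ces_asv_table` whose metadata records each
#'   sample's time point) and `truth` (target trajectories, fixed ASV
#'   splits, realized per-sample compositions, scenario).
#' @export
gen_asv_tables <- function(scenario = community_scenario()) {
  stopifnot(inherits(scenario, "ces_community_scenario"))
  with_seed(scenario$seed, {
    genera <- rownames(scenario$trajectories)
    k <- scenario$asvs_per_genus
    splits <- matrix(scenario$within_genus_split, nrow = length(genera),
                     ncol = k, byrow = TRUE, dimnames = list(genera, NULL))
    asv_ids <- as.vector(t(outer(genera, seq_len(k), function(g, i) {
      sprintf("ASV_%s_%d", g, i)
    })))
    asv_genus <- rep(genera, each = k)

    samples <- character(0)
    tps <- character(0)
    counts <- NULL
    realized <- list()
    for (i in seq_along(scenario$time_points)) {
      base_p <- as.vector(t(splits * scenario$trajectories[, i]))
      for (r in seq_len(scenario$n_replicates)) {
        sample_id <- sprintf("%s_r%d", scenario$time_points[i], r)
        p <- rdirichlet1(scenario$concentration * base_p)
        x <- stats::rmultinom(1, scenario$total_reads, p)[, 1]
        counts <- cbind(counts, x)
        samples <- c(samples, sample_id)
        tps <- c(tps, scenario$time_points[i])
        realized[[sample_id]] <- stats::setNames(p, asv_ids)
      }
    }
    dimnames(counts) <- list(asv_ids, samples)
    tab <- asv_table(
      counts,
      taxonomy = genus_lineage(asv_genus),
      metadata = data.frame(sample = samples, time_point = tps,
                            stringsAsFactors = FALSE)
    )
    list(table = tab,
         truth = list(trajectories = scenario$trajectories,
                      within_genus_split = splits,
                      realized_proportions = realized,
                      scenario = scenario))
  })
}
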