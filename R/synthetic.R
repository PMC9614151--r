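# Desk-scale synthetic benchmark with the statistical structure the model
# assumes: character sequences for both branches, a pair-level interaction
# rule planted as the conjunction of two motifs (a signal neither branch can
# resolve alone), and skewed continuous affinities for the discretization
# scheme.

.drug_alphabet <- c("C", "c", "N", "n", "O", "o", "S", "s", "F", "P",
                    "(", ")", "=", "#", "1", "2")
.protein_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Specification of a synthetic interaction study
#'
#' Defaults define the package's reference study conditions: 200 drugs and
#' 200 proteins, 4,000 sampled pairs, drug lengths 20-60 and protein lengths
#' 80-200, one short motif per branch planted in half of each library,
#' interaction = both motifs present (AND rule), and 5% label noise.
#'
#' @param n_drugs,n_proteins Library sizes.
#' @param n_pairs Distinct (drug, protein) pairs to sample.
#' @param drug_len_range,protein_len_range Inclusive length intervals.
#' @param motif_drug,motif_protein Planted motifs (shorter than the minimum
#'   sequence lengths).
#' @param interaction_rule Only `"and_motifs"` is defined.
#' @param label_noise Independent label-flip probability in `[0, 0.5]`.
#' @param seed Generator seed.
#' @return A validated `dpi_synthetic_spec` list.
#' @export
synthetic_spec <- function(n_drugs = 200L, n_proteins = 200L, n_pairs = 4000L,
                           drug_len_range = c(20L, 60L),
                           protein_len_range = c(80L, 200L),
                           motif_drug = "C(=O)N", motif_protein = "HWKHW",
                           interaction_rule = "and_motifs",
                           label_noise = 0.05, seed = 0L) {
  spec <- list(n_drugs = as.integer(n_drugs),
               n_proteins = as.integer(n_proteins),
               n_pairs = as.integer(n_pairs),
               drug_len_range = as.integer(drug_len_range),
               protein_len_range = as.integer(protein_len_range),
               motif_drug = motif_drug, motif_protein = motif_protein,
               interaction_rule = match.arg(interaction_rule, "and_motifs"),
               label_noise = label_noise, seed = as.integer(seed))
  stopifnot(spec$n_drugs >= 1L, spec$n_proteins >= 1L, spec$n_pairs >= 1L,
            spec$n_pairs <= spec$n_drugs * spec$n_proteins,
            spec$drug_len_range[1L] >= nchar(spec$motif_drug),
            spec$protein_len_range[1L] >= nchar(spec$motif_protein),
            spec$drug_len_range[1L] <= spec$drug_len_range[2L],
            spec$protein_len_range[1L] <= spec$protein_len_range[2L],
            spec$label_noise >= 0, spec$label_noise <= 0.5)
  structure(spec, class = "dpi_synthetic_spec")
}

random_sequences <- function(n, len_range, alphabet) {
  lens <- sample(seq(len_range[1L], len_range[2L]), n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1L))
}

plant_motif <- function(seqs, motif, carriers) {
  ml <- nchar(motif)
  for (i in which(carriers)) {
    L <- nchar(seqs[i])
    pos <- sample.int(L - ml + 1L, 1L)
    substr(seqs[i], pos, pos + ml - 1L) <- motif
  }
  seqs
}

#' Generate the drug and protein libraries
#'
#' Drugs are drawn character-wise from a 16-symbol SMILES-like alphabet,
#' proteins from the 20 standard amino acids, with lengths uniform in their
#' configured ranges; each branch's motif is overwritten at a random
#' position into a seeded 50% subset of its library.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `drugs`, `proteins` (character vectors), `drug_has_motif`,
#'   `protein_has_motif` (logical carrier flags as planted).
#' @export
generate_sequences <- function(spec) {
  stopifnot(inherits(spec, "dpi_synthetic_spec"))
  set.seed(spec$seed)
  drugs <- random_sequences(spec$n_drugs, spec$drug_len_range, .drug_alphabet)
  proteins <- random_sequences(spec$n_proteins, spec$protein_len_range,
                               .protein_alphabet)
  d_car <- sample(c(TRUE, FALSE), spec$n_drugs, replace = TRUE)
  p_car <- sample(c(TRUE, FALSE), spec$n_proteins, replace = TRUE)
  drugs <- plant_motif(drugs, spec$motif_drug, d_car)
  proteins <- plant_motif(proteins, spec$motif_protein, p_car)
  list(drugs = drugs, proteins = proteins,
       drug_has_motif = grepl(spec$motif_drug, drugs, fixed = TRUE),
       protein_has_motif = grepl(spec$motif_protein, proteins, fixed = TRUE))
}

#' Sample labeled interaction records
#'
#' Samples `n_pairs` distinct (drug, protein) pairs; the noise-free rule
#' label is 1 iff the drug carries the drug motif AND the protein carries
#' the protein motif (determined from sequence content), after which each
#' observed label flips independently with probability `label_noise`. Both
#' labels are returned so a study can score recovery of the generating rule
#' separately from agreement with the noisy observations.
#'
#' @param seqs Output of [generate_sequences()].
#' @param spec The same [synthetic_spec()].
#' @return Data frame: `drug_id`, `protein_id`, `drug`, `protein`, `label`
#'   (observed, possibly flipped), `label_true` (noise-free rule label).
#' @export
generate_interactions <- function(seqs, spec) {
  stopifnot(inherits(spec, "dpi_synthetic_spec"))
  nd <- spec$n_drugs; np <- spec$n_proteins
  set.seed(spec$seed + 1L)
  cell <- sample.int(nd * np, spec$n_pairs)   # distinct pairs
  di <- ((cell - 1L) %% nd) + 1L
  pi_ <- ((cell - 1L) %/% nd) + 1L
  truth <- as.integer(seqs$drug_has_motif[di] & seqs$protein_has_motif[pi_])
  flip <- stats::runif(spec$n_pairs) < spec$label_noise
  data.frame(drug_id = di, protein_id = pi_,
             drug = seqs$drugs[di], protein = seqs$proteins[pi_],
             label = as.integer(xor(truth == 1L, flip)),
             label_true = truth,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic interaction dataset
#'
#' Convenience wrapper: sequences plus interaction records in one call.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `sequences`, `pairs` (see [generate_interactions()]),
#'   `spec`.
#' @export
generate_dpi_dataset <- function(spec = synthetic_spec()) {
  seqs <- generate_sequences(spec)
  list(sequences = seqs, pairs = generate_interactions(seqs, spec),
       spec = spec)
}

#' Draw continuous affinities from a Gaussian mixture
#'
#' Emulates the skewed affinity histograms of kinase panels: a dominant
#' low-affinity mode plus a smaller high-affinity tail. Defaults draw 85%
#' from N(5, 0.6^2) and 15% from N(8, 1.2^2), roughly the shape of a pKd
#' column.
#'
#' @param n Number of draws.
#' @param means,sds Component means and standard deviations.
#' @param weights Component weights (sum to 1).
#' @param seed Seed.
#' @return Numeric vector of length `n`.
#' @export
generate_affinities <- function(n, means = c(5, 8), sds = c(0.6, 1.2),
                                weights = c(0.85, 0.15), seed = 0L) {
  stopifnot(length(means) == length(sds), length(sds) == length(weights),
            all(sds > 0), abs(sum(weights) - 1) < 1e-8, n >= 1L)
  set.seed(seed)
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  stats::rnorm(n, mean = means[comp], sd = sds[comp])
}
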