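# Packaged literature tables and the synthetic-data generator.
#
# The packaged tables store the printed values of the two
# structure-activity case studies (a CDK2 aminothiazole series and an
# 11beta-HSD1 pyrazolopyrimidine series) plus the water calibration
# reference; they are stored verbatim, never recomputed.

FIXTURE_NAMES <- c("table1_cdk2_activities", "table2_cdk2_strengths",
                   "table3_cdk2_correlations", "table4_hsd1_activities",
                   "table5_hsd1_strengths", "table6_hsd1_correlations",
                   "water_reference")

#' Load a packaged fixture table
#'
#' @param name One of `table1_cdk2_activities`, `table2_cdk2_strengths`,
#'   `table3_cdk2_correlations`, `table4_hsd1_activities`,
#'   `table5_hsd1_strengths`, `table6_hsd1_correlations`,
#'   `water_reference`.
#' @return A data.frame with the printed values.
#' @export
load_fixture <- function(name) {
  if (!name %in% FIXTURE_NAMES) {
    stop("unknown fixture '", name, "'; available: ",
         paste(FIXTURE_NAMES, collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "hbhydro")
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read an experimental hydration dataset
#'
#' Expects columns `id`, `smiles`, `dG_exp_kj_mol` (or `dG_exp_kcal_mol`,
#' converted by the thermochemical factor 4.184). Extra columns are kept.
#'
#' @param path CSV file path.
#' @return data.frame with `id`, `smiles`, `dG_exp_kj_mol`.
#' @export
read_dataset_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"dG_exp_kj_mol" %in% names(d)) {
    if ("dG_exp_kcal_mol" %in% names(d)) {
      d$dG_exp_kj_mol <- d$dG_exp_kcal_mol * 4.184
    } else {
      stop("dataset needs a dG_exp_kj_mol (or dG_exp_kcal_mol) column",
           call. = FALSE)
    }
  }
  if (!all(c("id", "smiles") %in% names(d))) {
    stop("dataset needs 'id' and 'smiles' columns", call. = FALSE)
  }
  d
}

# seeded fragment grammar over MMFF94-parameterised chemistry:
# [aromatic head] + carbon chain with optional in-chain O/N + terminal
# polar/halogen group
sample_grammar_smiles <- function(n) {
  heads <- c("", "", "c1ccccc1")
  terminals <- c("", "O", "N", "Cl", "F", "OC", "C#N")
  vapply(seq_len(n), function(k) {
    head <- sample(heads, 1)
    len <- sample(if (nzchar(head)) 0:4 else 2:6, 1)
    chain <- strsplit(strrep("C", len), "")[[1]]
    if (len >= 3 && stats::runif(1) < 0.4) {
      pos <- sample(2:(len - 1), 1)
      chain[pos] <- sample(c("O", "N"), 1)
    }
    smi <- paste0(head, paste(chain, collapse = ""),
                  sample(terminals, 1))
    if (!nzchar(smi)) smi <- "CC"
    smi
  }, character(1))
}

#' Generate a synthetic (molecule, energy) dataset from the model itself
#'
#' Molecules are enumerated from a seeded fragment grammar (alkanes,
#' alcohols, amines, ethers, nitriles, halides, simple aromatics), fully
#' prepared (embedded, MMFF94-minimised, charged), and labelled with the
#' model's own prediction under `params` plus Gaussian noise. Useful as a
#' fitting-recovery oracle: at `noise_sd = 0` the generating parameters
#' reproduce the labels exactly.
#'
#' @param n Number of molecules.
#' @param seed Integer seed controlling grammar, embedding and noise.
#' @param params Generating [hydration_params()].
#' @param noise_sd Gaussian noise standard deviation, kJ/mol.
#' @return List with `records` (prepared, charged `mol_record`s),
#'   `dg` (noisy labels, kJ/mol), `dg_model` (noise-free predictions) and
#'   `table` (data.frame id, smiles, dG_exp_kj_mol).
#' @export
generate_synthetic_dataset <- function(n, seed = 1L,
                                       params = hydration_params(),
                                       noise_sd = 0) {
  stopifnot(n >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(seed)
  smiles <- sample_grammar_smiles(n)
  path <- tempfile(fileext = ".smi")
  writeLines(sprintf("%s syn%03d", smiles, seq_len(n)), path)
  records <- load_molecules(path, "smiles")
  records <- prepare_conformers(records, seed = seed)
  records <- lapply(records, compute_charges_radii)
  pred <- predict_hydration(records, params)
  stopifnot(nrow(pred) == n)  # grammar guarantees preparable molecules
  noise <- stats::rnorm(n, 0, noise_sd)
  dg <- pred$dG_total + noise
  list(records = records, dg = dg, dg_model = pred$dG_total,
       table = data.frame(id = pred$id,
                          smiles = vapply(records, `[[`, character(1),
                                          "smiles"),
                          dG_exp_kj_mol = dg))
}
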