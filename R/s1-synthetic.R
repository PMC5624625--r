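# Synthetic stand-in for a published species/trait supplementary table.
# The original checklist (126 woody species with five traits and
# per-transect occurrence on four transects) is distributed only as a
# spreadsheet; the file shipped under inst/extdata is a fully synthetic
# reconstruction whose *marginal counts* are constrained to the printed
# summary numbers (126 species in 73 genera and 44 families; 72 / 91 / 66 /
# 58 species on transects SOS / SSI / BBA / BBO), while species names and
# trait values are generated. It exists so the loading / counting / PCA
# machinery has a fixed reference input of realistic shape.

#' Generate the synthetic S1-style species/trait reference table
#'
#' Deterministic (internally seeded): the generated table is the one
#' shipped at `inst/extdata/s1_synthetic_species.tsv`, and the test suite
#' asserts the round trip. Columns: `species_id`, `genus`, `family`, the
#' five [trait_vars()], and one 0/1 occurrence column per transect
#' (`SOS`, `SSI`, `BBA`, `BBO`).
#'
#' @return data.frame with 126 rows.
#' @export
make_s1_synthetic <- function() {
  n_sp <- 126; n_gen <- 73; n_fam <- 44
  genus_of <- ((seq_len(n_sp) - 1) %% n_gen) + 1
  family_of_genus <- ((seq_len(n_gen) - 1) %% n_fam) + 1
  sets <- list(SOS = 1:72, SSI = c(1:60, 96:126),
               BBA = 40:105, BBO = 55:112)
  occ <- sapply(sets, function(s) as.integer(seq_len(n_sp) %in% s))

  # plausible cross-trait correlation on the log scale: tall species have
  # longer/wider leaves and heavier seeds; flowering onset nearly free
  R <- rbind(c(1.00, 0.40, 0.35, 0.10, 0.30),
             c(0.40, 1.00, 0.60, 0.10, 0.20),
             c(0.35, 0.60, 1.00, 0.10, 0.20),
             c(0.10, 0.10, 0.10, 1.00, 0.05),
             c(0.30, 0.20, 0.20, 0.05, 1.00))
  set.seed(126073L)
  Z <- matrix(rnorm(n_sp * 5), n_sp, 5) %*% chol(R)
  traits <- data.frame(
    max_height = round(exp(log(8) + 0.9 * Z[, 1]), 2),
    leaf_length = round(exp(log(7) + 0.6 * Z[, 2]), 2),
    leaf_width = round(exp(log(4) + 0.6 * Z[, 3]), 2),
    flowering_onset = pmin(12, pmax(1, round(5.5 + 1.6 * Z[, 4]))),
    seed_mass = round(exp(log(20) + 1.5 * Z[, 5]), 3))
  data.frame(
    species_id = sprintf("synsp_%03d", seq_len(n_sp)),
    genus = sprintf("syngen_%02d", genus_of),
    family = sprintf("synfam_%02d", family_of_genus[genus_of]),
    traits, occ, stringsAsFactors = FALSE)
}

#' Read an S1-style species/trait table
#'
#' @param path delimited file in the [make_s1_synthetic()] layout.
#' @return data.frame.
#' @export
read_s1_table <- function(path) {
  df <- read_table_auto(path)
  need <- c("species_id", "genus", "family", trait_vars())
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("S1-style table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$species_id)) stop("duplicate species ids")
  df
}

#' Summary counts of an S1-style table
#'
#' @param s1 data.frame from [read_s1_table()].
#' @param transects occurrence column names to count over.
#' @return list: `n_species`, `n_genera`, `n_families`, `per_transect`
#'   (named species counts).
#' @export
s1_counts <- function(s1, transects = c("SOS", "SSI", "BBA", "BBO")) {
  transects <- intersect(transects, names(s1))
  list(n_species = nrow(s1),
       n_genera = length(unique(s1$genus)),
       n_families = length(unique(s1$family)),
       per_transect = vapply(setNames(transects, transects),
                             function(tr) sum(s1[[tr]] > 0), numeric(1)))
}
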