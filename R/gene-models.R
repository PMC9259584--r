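#' Default per-gene mutation models for the synthetic cohort
#'
#' Frequencies follow the printed pediatric/adult mutation rates of the
#' recurrently mutated Burkitt lymphoma genes: `p_young`/`p_old` are the
#' plateau mutation probabilities in children and older adults (female
#' baseline where a sex bias applies), `sex_odds_male` multiplies the odds
#' of carrying a mutation for male patients (DDX3X, an X-linked helicase,
#' is strongly male-biased), and `mean_muts_if_mutated` sets the expected
#' number of distinct SNV/indels per mutated case (MYC accumulates several
#' per case through aberrant somatic hypermutation).
#'
#' @return Tibble with columns `gene`, `p_young`, `p_old`, `sex_odds_male`,
#'   `mean_muts_if_mutated`.
#' @export
default_gene_models <- function() {
  tribble(
    ~gene,      ~p_young, ~p_old, ~sex_odds_male, ~mean_muts_if_mutated,
    "ID3",        0.76,    0.40,   1,   1.7,
    "MYC",        0.55,    0.60,   1,   2.9,
    "TP53",       0.30,    0.30,   1,   1.2,
    "CCND3",      0.25,    0.25,   1,   1.15,
    "SMARCA4",    0.35,    0.21,   1,   1.15,
    "DDX3X",      0.04,    0.015, 20,   1.1,
    "ARID1A",     0.32,    0.19,   1,   1.2,
    "FBXO11",     0.22,    0.10,   1,   1.1,
    "GNA13",      0.19,    0.07,   1,   1.1,
    "FOXO1",      0.15,    0.08,   1,   1.1,
    "TCF3",       0.12,    0.08,   1,   1.1,
    "PCBP1",      0.10,    0.08,   1,   1.0,
    "P2RY8",      0.12,    0.10,   1,   1.0,
    "PTEN",       0.08,    0.02,   1,   1.0,
    "BCL2",       0.00,    0.11,   1,   1.3,
    "YY1AP1",     0.02,    0.16,   1,   1.2,
    "PIM1",       0.005,   0.07,   1,   1.0,
    "CREBBP",     0.02,    0.10,   1,   1.0,
    "CARD11",     0.005,   0.05,   1,   1.0,
    "SOCS1",      0.01,    0.06,   1,   1.0,
    "DTX1",       0.005,   0.05,   1,   1.0,
    "BTG2",       0.01,    0.08,   1,   1.0,
    "TFAP4",      0.08,    0.06,   1,   1.0,
    "EBF1",       0.05,    0.05,   1,   1.0,
    "HIST1H1E",   0.05,    0.05,   1,   1.0,
    "RHOA",       0.04,    0.04,   1,   1.0,
    "KMT2D",      0.06,    0.06,   1,   1.0,
    "POU2F2",     0.03,    0.03,   1,   1.0,
    "TET2",       0.03,    0.05,   1,   1.0,
    "SGK1",       0.04,    0.04,   1,   1.0,
    "CCNF",       0.03,    0.03,   1,   1.0,
    "TMSB4X",     0.03,    0.03,   1,   1.0,
    "ZFP36L1",    0.02,    0.02,   1,   1.0
  )
}

# panel gene loci used to place synthetic variants (GRCh38-scale
# coordinates; the ID3 locus matches the region used in validation work)
gene_loci <- function() {
  tribble(
    ~gene,      ~chrom, ~start,     ~end,
    "ID3",      "1",    23557000,   23559800,
    "MYC",      "8",    127735000,  127742000,
    "TP53",     "17",   7668000,    7688000,
    "CCND3",    "6",    41934000,   41956000,
    "SMARCA4",  "19",   10960000,   11065000,
    "DDX3X",    "X",    41333000,   41365000,
    "ARID1A",   "1",    26693000,   26782000,
    "FBXO11",   "2",    47806000,   47906000,
    "GNA13",    "17",   65000000,   65050000,
    "FOXO1",    "13",   40555000,   40666000,
    "TCF3",     "19",   1609000,    1652000,
    "PCBP1",    "2",    70314000,   70316500,
    "P2RY8",    "X",    1462000,    1537000,
    "PTEN",     "10",   87863000,   87971000,
    "BCL2",     "18",   63123000,   63320000,
    "YY1AP1",   "1",    155669000,  155697000,
    "PIM1",     "6",    37170000,   37177000,
    "CREBBP",   "16",   3725000,    3880000,
    "CARD11",   "7",    2906000,    3043000,
    "SOCS1",    "16",   11254000,   11256500,
    "DTX1",     "12",   113057000,  113098000,
    "BTG2",     "1",    203305000,  203309000,
    "TFAP4",    "16",   4257000,    4273000,
    "EBF1",     "5",    158695000,  159099000,
    "HIST1H1E", "6",    26156000,   26158000,
    "RHOA",     "3",    49359000,   49412000,
    "KMT2D",    "12",   49018000,   49060000,
    "POU2F2",   "19",   41925000,   42017000,
    "TET2",     "4",    105145000,  105280000,
    "SGK1",     "6",    134169000,  134318000,
    "CCNF",     "16",   2429000,    2460000,
    "TMSB4X",   "X",    12975000,   12978000,
    "ZFP36L1",  "14",   68787000,   68796000,
    "GPC5",     "13",   91398619,   92867237
  )
}

#' Age- and sex-dependent mutation probability
#'
#' The probability of carrying a mutation in a gene follows a logistic
#' transition in age between the pediatric plateau `p_young` and the adult
#' plateau `p_old`, centered at `a0` with width `w`; male sex multiplies
#' the carrier odds by `sex_odds_male`.
#'
#' @param age Age in years.
#' @param sex `"female"` or `"male"`.
#' @param p_young,p_old Plateau probabilities (female baseline).
#' @param sex_odds_male Odds multiplier for males.
#' @param a0 Transition center in years (default 35).
#' @param w Transition width in years (default 5).
#' @return Numeric vector of probabilities.
#' @export
mutation_probability <- function(age, sex, p_young, p_old, sex_odds_male = 1,
                                 a0 = 35, w = 5) {
  p <- p_young + (p_old - p_young) * stats::plogis((age - a0) / w)
  male <- sex == "male"
  if (any(male) && any(sex_odds_male != 1)) {
    odds <- p / (1 - p) * sex_odds_male
    p_m <- odds / (1 + odds)
    p_m[p == 1] <- 1
    p <- if_else(male, p_m, p)
  }
  p
}
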