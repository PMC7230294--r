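# Builds inst/extdata/default_panel.csv: a 188-metabolite targeted panel with the
# class composition of a Biocrates-p180-style kit. Metabolite identities follow the
# field's naming conventions; quantitation limits are plausible per-class values,
# varied deterministically, not vendor values.
suppressPackageStartupMessages(library(tibble))

amino_acids <- c("Ala", "Arg", "Asn", "Asp", "Cit", "Gln", "Glu", "Gly", "His",
                 "Ile", "Leu", "Lys", "Met", "Orn", "Phe", "Pro", "Ser", "Thr",
                 "Trp", "Tyr", "Val")
stopifnot(length(amino_acids) == 21)

biogenic_amines <- c("Ac-Orn", "ADMA", "SDMA", "total DMA", "alpha-AAA",
                     "Carnosine", "Creatinine", "DOPA", "Dopamine", "Histamine",
                     "Kynurenine", "Met-SO", "Nitro-Tyr", "c4-OH-Pro",
                     "t4-OH-Pro", "PEA", "Putrescine", "Sarcosine", "Serotonin",
                     "Spermidine", "Spermine")
stopifnot(length(biogenic_amines) == 21)

acylcarnitines <- c("C2", "C3", "C3:1", "C3-OH", "C3-DC", "C4", "C4:1", "C4-OH",
                    "C5", "C5:1", "C5:1-DC", "C5-OH", "C5-DC", "C5-M-DC", "C6",
                    "C6:1", "C7-DC", "C8", "C9", "C10", "C10:1", "C10:2", "C12",
                    "C12:1", "C12-DC", "C14", "C14:1", "C14:1-OH", "C14:2",
                    "C14:2-OH", "C16", "C16:1", "C16:1-OH", "C16:2", "C16:2-OH",
                    "C16-OH", "C18", "C18:1", "C18:2")
stopifnot(length(acylcarnitines) == 39)

lpc_chain <- c(14, 16, 16, 17, 18, 18, 18, 20, 20, 24, 26, 26, 28, 28)
lpc_sat   <- c(0, 0, 1, 0, 0, 1, 2, 3, 4, 0, 0, 1, 0, 1)
lysoPC <- sprintf("lysoPC a C%d:%d", lpc_chain, lpc_sat)
stopifnot(length(lysoPC) == 14, !anyDuplicated(lysoPC))

pc_aa <- paste("PC aa", c("C24:0", "C26:0", "C28:1", "C30:0", "C30:2", "C32:0",
                          "C32:1", "C32:2", "C32:3", "C34:1", "C34:2", "C34:3",
                          "C34:4", "C36:0", "C36:1", "C36:2", "C36:3", "C36:4",
                          "C36:5", "C36:6", "C38:0", "C38:1", "C38:3", "C38:4",
                          "C38:5", "C38:6", "C40:1", "C40:2", "C40:3", "C40:4",
                          "C40:5", "C40:6", "C42:0", "C42:1", "C42:2", "C42:4",
                          "C42:5", "C42:6"))
stopifnot(length(pc_aa) == 38)

pc_ae <- paste("PC ae", c("C30:0", "C30:1", "C30:2", "C32:1", "C32:2", "C34:0",
                          "C34:1", "C34:2", "C34:3", "C36:0", "C36:1", "C36:2",
                          "C36:3", "C36:4", "C36:5", "C38:0", "C38:1", "C38:2",
                          "C38:3", "C38:4", "C38:5", "C38:6", "C40:1", "C40:2",
                          "C40:3", "C40:4", "C40:5", "C40:6", "C42:0", "C42:1",
                          "C42:2", "C42:3", "C42:4", "C42:5", "C44:3", "C44:4",
                          "C44:5", "C44:6"))
stopifnot(length(pc_ae) == 38)

sm <- c("SM C16:0", "SM C16:1", "SM C18:0", "SM C18:1", "SM C20:2", "SM C22:3",
        "SM C24:0", "SM C24:1", "SM C26:0", "SM C26:1", "SM (OH) C14:1",
        "SM (OH) C16:1", "SM (OH) C22:1", "SM (OH) C22:2", "SM (OH) C24:1")
stopifnot(length(sm) == 15)

panel <- rbind(
  tibble(metabolite_id = "C0", class = "free_carnitine", acyl_carbons = NA_integer_),
  tibble(metabolite_id = acylcarnitines, class = "acylcarnitine", acyl_carbons = NA_integer_),
  tibble(metabolite_id = "H1", class = "hexose", acyl_carbons = NA_integer_),
  tibble(metabolite_id = amino_acids, class = "amino_acid", acyl_carbons = NA_integer_),
  tibble(metabolite_id = biogenic_amines, class = "biogenic_amine", acyl_carbons = NA_integer_),
  tibble(metabolite_id = lysoPC, class = "lysoPC", acyl_carbons = as.integer(lpc_chain)),
  tibble(metabolite_id = pc_aa, class = "PC_aa", acyl_carbons = NA_integer_),
  tibble(metabolite_id = pc_ae, class = "PC_ae", acyl_carbons = NA_integer_),
  tibble(metabolite_id = sm, class = "sphingomyelin", acyl_carbons = NA_integer_)
)
stopifnot(nrow(panel) == 188, !anyDuplicated(panel$metabolite_id))

# Per-class typical quantitation ranges (uM), spread deterministically across the
# class so limits differ metabolite to metabolite.
base <- list(
  free_carnitine = c(1, 500), acylcarnitine = c(0.02, 25), hexose = c(100, 5e4),
  amino_acid = c(2, 1500), biogenic_amine = c(0.05, 150), lysoPC = c(0.1, 400),
  PC_aa = c(0.05, 600), PC_ae = c(0.02, 300), sphingomyelin = c(0.05, 400)
)
set.seed(188)
panel$lloq <- panel$uloq <- NA_real_
for (cl in names(base)) {
  idx <- which(panel$class == cl)
  mult <- round(exp(runif(length(idx), log(0.5), log(2))), 3)
  panel$lloq[idx] <- signif(base[[cl]][1] * mult, 3)
  panel$uloq[idx] <- signif(base[[cl]][2] * mult, 3)
}
stopifnot(all(panel$lloq > 0), all(panel$uloq > panel$lloq))

panel <- panel[, c("metabolite_id", "class", "lloq", "uloq", "acyl_carbons")]
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
readr::write_csv(panel, "inst/extdata/default_panel.csv")
cat("wrote", nrow(panel), "rows\n")
print(table(panel$class))
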