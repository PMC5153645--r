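#!/usr/bin/env Rscript
# Receptor classification: motif-anchor calls (inotocin-like vs
# CCAP-like) over the receptor candidates, plus a neighbour-joining
# grouping check over pairwise alignment identities.

suppressMessages(library(inotoscan))

config <- generator_config(seed = 20161209L, n_species = 20L,
                           decoy_count = 50L, mutation_rate = 0.02,
                           truncation_prob = 0.15)
dataset <- generate_dataset(config)
hits <- search_dataset(reference_queries()[2, ], dataset$records,
                       scoring_scheme())
cand <- dataset$records[dataset$records$id %in% hits$subject_id, ]
calls <- classify_receptors(cand, partial = nchar(cand$residues) < 250)

dir.create("results", showWarnings = FALSE)
write.table(calls, "results/receptor_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Classified", nrow(calls), "receptor candidates:\n")
print(table(calls$label))

agree <- merge(calls, dataset$truth, by = "record_id")
is_rec <- grepl("^receptor", agree$class_label)
ok <- with(agree[is_rec, ],
           (class_label == "receptor_inotocin" &
              label == "inotocin_like") |
           (class_label == "receptor_ccap" & label == "ccap_like"))
cat("Calls agreeing with ground truth:", sum(ok), "/", sum(is_rec),
    "true receptors;", sum(!is_rec),
    "non-receptor candidate(s) left unclassified:",
    all(agree$label[!is_rec] == "unclassified"), "\n")

# grouping check over classified full-length receptors
grp <- calls$record_id[calls$label != "unclassified" & !calls$partial]
if (length(grp) >= 3) {
  tree <- pairwise_identity_tree(cand[cand$id %in% grp, ])
  ape::write.tree(tree, "results/receptor_nj.nwk")
  ino <- intersect(grp, calls$record_id[calls$label == "inotocin_like"])
  ccap <- intersect(grp, calls$record_id[calls$label == "ccap_like"])
  cat("NJ tree written; inotocin-like monophyletic:",
      length(ino) > 1 && ape::is.monophyletic(tree, ino),
      "; CCAP-like monophyletic:",
      length(ccap) > 1 && ape::is.monophyletic(tree, ccap), "\n")
}
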