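#!/usr/bin/env Rscript
# Accessible-contact-volume screening: predict mean inter-dye distances for
# the two toy stacking registers and rank them against a distance set
# generated by register 1.

library(fiberFRET)

pair <- dye_pair(82, 3.8, "Alexa568/647")
toy <- toy_register_geometry()
sc <- screen_toy_registers(toy, pair, generator = "register1", dR = 3)
print(sc$model_distances)
print(sc$ranking)
cat(sprintf("generating register ranks %d\n",
            sc$ranking$rank[sc$ranking$structure == "register1"]))
write.table(sc$ranking, "results/07_screen_ranking.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
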