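#!/usr/bin/env Rscript
## Regenerates the bone template fixture shipped under inst/extdata.
## Run from the package root: Rscript tools/make_templates.R

pkgload::load_all(".", quiet = TRUE)
dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
tpl <- buildWristTemplates()
carpalign:::.templatesToJSON(tpl, "inst/extdata/wrist_templates.json")
cat("wrote inst/extdata/wrist_templates.json\n")
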