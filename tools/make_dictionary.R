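# Regenerates inst/extdata/maps_srts_dictionary.json from the in-package
# dictionary builder. Run from the package root after editing R/dictionary.R:
#   Rscript tools/make_dictionary.R
pkgload::load_all(".", quiet = TRUE)
dict <- mapsrts:::build_default_dictionary()
out <- file.path("inst", "extdata", "maps_srts_dictionary.json")
dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
mapsrts::write_schema(dict, out)
cat("wrote", out, "\n")
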