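.datatable.aware <- TRUE

#' @importFrom data.table :=
NULL

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c("bucket", "text", "wmins", "link", "color",
                         "minimizer", "kmer", "gmin", "id", "side", ".N"))
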