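#' @importFrom data.table := .N data.table fread fwrite rbindlist dcast
#' @importFrom stats setNames
NULL

.datatable.aware <- TRUE

utils::globalVariables(c("canon", "grp", "pid"))
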