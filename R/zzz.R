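#' @keywords internal
"_PACKAGE"

# non-standard-evaluation column names used inside ggplot2::aes()
utils::globalVariables(c("offset", "site", "value", "group", "log2fc",
                         "PC1", "PC2", "orientation"))
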