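# Classed error conditions so callers can distinguish failure modes.

np_stop <- function(class, message, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "neuropep_error", "error"),
                      call = call))
}

np_duplicate_id_error <- function(msg) np_stop("neuropep_duplicate_id_error", msg)
np_alphabet_error     <- function(msg) np_stop("neuropep_alphabet_error", msg)
np_parse_error        <- function(msg) np_stop("neuropep_parse_error", msg)
np_usage_error        <- function(msg) np_stop("neuropep_usage_error", msg)
np_schema_error       <- function(msg) np_stop("neuropep_schema_error", msg)
np_value_error        <- function(msg) np_stop("neuropep_value_error", msg)
np_spec_error         <- function(msg) np_stop("neuropep_spec_error", msg)
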