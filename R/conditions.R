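# Structured conditions. Three families map onto CLI exit codes:
#   apcie_validation_error     -> 2 (bad inputs, schema, lookup, dimensions)
#   apcie_identification_error -> 3 (null space not one-dimensional)
#   apcie_convergence_error    -> 4 (IRLS failed to converge)

abort_apcie <- function(message, class, ...) {
  stop(structure(
    class = c(class, "apcie_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

abort_validation <- function(message, subclass = NULL, ...) {
  abort_apcie(message, c(subclass, "apcie_validation_error"), ...)
}

abort_identification <- function(message, ...) {
  abort_apcie(message, "apcie_identification_error", ...)
}

abort_convergence <- function(message, ...) {
  abort_apcie(message, "apcie_convergence_error", ...)
}
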