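#' Standard 19-channel 10-20 montage
#'
#' Electrode labels of the international 10-20 system as recorded by a
#' 19-channel clinical amplifier referenced to linked ears (A1+A2).
#'
#' @param channel_names Character vector of exactly 19 unique electrode labels.
#' @param reference Reference label, by default the linked-ears `"A1+A2"`.
#' @return An object of class `montage_spec`.
#' @export
#' @examples
#' m <- montage_1020()
#' m$channel_names
montage_spec <- function(channel_names, reference = "A1+A2") {
  if (length(channel_names) != 19L) {
    stop("a 10-20 montage_spec requires exactly 19 channels, got ",
         length(channel_names), call. = FALSE)
  }
  if (anyDuplicated(channel_names)) {
    stop("channel names must be unique", call. = FALSE)
  }
  structure(
    list(channel_names = as.character(channel_names),
         reference = reference),
    class = "montage_spec"
  )
}

#' @rdname montage_spec
#' @export
montage_1020 <- function() {
  montage_spec(c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                 "T3", "C3", "Cz", "C4", "T4",
                 "T5", "P3", "Pz", "P4", "T6", "O1", "O2"))
}

#' @export
print.montage_spec <- function(x, ...) {
  cat("<montage_spec> ", length(x$channel_names), " channels, ref ",
      x$reference, "\n", sep = "")
  cat(" ", paste(x$channel_names, collapse = " "), "\n")
  invisible(x)
}
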