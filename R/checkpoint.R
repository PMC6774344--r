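# Plain-text checkpoint/restart of a field_state: a small metadata header
# followed by one row per DOF (cation, anion, potential).

#' Write a field-state checkpoint
#'
#' @param state A [field_state()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "field_state"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# pnpgel field_state checkpoint",
               sprintf("# time_s %.17g", state$time),
               sprintf("# ndof %d", length(state$potential)),
               "# cation_mol_m3 anion_mol_m3 potential_V"), con)
  writeLines(paste(sprintf("%.17g", state$concentrations[, 1L]),
                   sprintf("%.17g", state$concentrations[, 2L]),
                   sprintf("%.17g", state$potential)), con)
  invisible(path)
}

#' Read a field-state checkpoint
#'
#' @param path Path written by [write_checkpoint()].
#' @return A [field_state()].
#' @export
read_checkpoint <- function(path) {
  txt <- readLines(path)
  hdr <- grep("^#", txt, value = TRUE)
  time <- as.numeric(sub("^# time_s ", "", grep("^# time_s", hdr,
                                                value = TRUE)))
  dat <- matrix(scan(text = txt[!grepl("^#", txt)], quiet = TRUE),
                ncol = 3L, byrow = TRUE)
  field_state(time, cbind(cation = dat[, 1L], anion = dat[, 2L]),
              dat[, 3L])
}
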