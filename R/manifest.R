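# Run provenance: a JSON manifest describing inputs, seed and model file
# content hash, written next to every command-line artifact set.

#' Write a run manifest
#'
#' Records what produced a set of result files: the command, input file
#' paths with MD5 content hashes, the seed and settings, and the package
#' version. Re-running a command with an identical manifest reproduces
#' byte-identical CSV outputs.
#'
#' @param path output JSON path.
#' @param command subcommand or analysis name.
#' @param inputs named character vector of input file paths (hashed).
#' @param settings named list of settings (seed, reps, steps, scheme, ...).
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(path, command, inputs = character(),
                           settings = list()) {
  hashes <- if (length(inputs))
    as.list(tools::md5sum(unname(inputs))) else list()
  names(hashes) <- names(inputs)
  manifest <- list(
    command = command,
    package = "sepsisBN",
    version = as.character(utils::packageVersion("sepsisBN")),
    inputs = as.list(inputs),
    input_md5 = hashes,
    settings = settings)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
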