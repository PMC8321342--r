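# One-shot and batch conversion: mol2 in, simulation XML out. This is the
# function behind the command-line script in inst/scripts/mol2narupa.R.

#' Convert mol2 files to simulation XML
#'
#' For each input: parse (strict or lenient), optionally balance
#' hydrogens and/or minimize bond lengths, build the simulation spec
#' (typed from a glossary when one is given) and write the XML next to
#' the input stem (or into \code{out_dir}). A failure on one file does
#' not stop the batch.
#'
#' @param inputs character vector of mol2 file paths.
#' @param out_dir output directory; default: each file's own directory.
#'   Created if absent.
#' @param mode \code{"lenient"} (default) or \code{"strict"} parsing.
#' @param temperature simulation temperature in kelvin (default 300).
#' @param glossary optional: an \code{"ff_glossary"} or a path to one.
#' @param balance run \code{\link{balance_hydrogens}} first (default
#'   FALSE).
#' @param minimize run \code{\link{minimize_bonds}} (default FALSE).
#' @param seed integer seed for hydrogen placement (default 0).
#' @param valence a \code{\link{valence_model}}.
#' @param lengths a \code{\link{bond_length_table}}.
#' @return data.frame report with one row per input: \code{input},
#'   \code{output} (NA on failure), \code{status} (\code{"ok"} /
#'   \code{"failed"}), \code{n_repairs}, \code{n_type_warnings},
#'   \code{message}. The attribute \code{"n_failed"} carries the failure
#'   count.
#' @export
convert_mol2_files <- function(inputs, out_dir = NULL,
                               mode = c("lenient", "strict"),
                               temperature = 300, glossary = NULL,
                               balance = FALSE, minimize = FALSE, seed = 0,
                               valence = valence_model(),
                               lengths = bond_length_table()) {
  mode <- match.arg(mode)
  if (is.character(glossary)) glossary <- load_glossary(glossary)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- lapply(inputs, function(path) {
    res <- tryCatch({
      doc <- read_mol2(path, mode = mode)
      mol <- doc$molecule
      if (balance) mol <- balance_hydrogens(mol, valence, lengths, seed)
      if (minimize) mol <- minimize_bonds(mol, lengths)$molecule
      viol <- validate_molecule(mol, valence)
      if (nrow(viol) > 0) {
        stop("validation failed: ", paste(viol$message, collapse = "; "))
      }
      spec <- build_spec(mol, temperature = temperature,
                         glossary = glossary)
      n_warn <- if (is.null(glossary)) 0L else
        length(assign_types(mol, glossary)$warnings)
      dest_dir <- if (is.null(out_dir)) dirname(path) else out_dir
      out <- file.path(dest_dir,
                       paste0(sub("\\.mol2$", "", basename(path)), ".xml"))
      write_simulation_xml(spec, path = out)
      data.frame(input = path, output = out, status = "ok",
                 n_repairs = length(doc$repairs),
                 n_type_warnings = n_warn, message = "",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(input = path, output = NA_character_, status = "failed",
                 n_repairs = NA_integer_, n_type_warnings = NA_integer_,
                 message = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(input = character(), output = character(),
               status = character(), n_repairs = integer(),
               n_type_warnings = integer(), message = character(),
               stringsAsFactors = FALSE)
  attr(report, "n_failed") <- sum(report$status == "failed")
  report
}
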