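# TRIPOS mol2 reading and writing.
#
# Two dialects are supported: standard dot-decimal mol2, and the comma-
# decimal dialect exported by Narupa Builder (coordinates like "-6,165").
# The dialect is auto-detected on read, recorded in the document and
# reproduced on write. Parsing is strict (any malformed record raises) or
# lenient (documented, logged repairs are applied where possible).

.MOL2_ORDER_TOKENS <- c("1", "2", "3", "ar", "am", "du", "un", "nc")

.normalize_order_token <- function(tok) {
  if (tok %in% c("du", "un", "nc")) "un" else tok
}

#' Construct a mol2 document
#'
#' Wraps a \code{\link{molecule}} together with the mol2 header metadata
#' (declared counts, molecule type, charge method) and the dialect used for
#' coordinates.
#'
#' @param molecule a \code{\link{molecule}}.
#' @param declared_counts integer vector \code{(n_atoms, n_bonds, n_subst,
#'   n_feat, n_sets)}; defaults to the actual counts and zeros.
#' @param mol_type MOLECULE-section type line (default \code{"SMALL"}).
#' @param charge_method charge-method line (default \code{"GASTEIGER"}).
#' @param dialect \code{"dot"} or \code{"comma"}.
#' @param repairs character vector of lenient-mode repair notes.
#' @return object of class \code{"mol2_document"}.
#' @export
mol2_document <- function(molecule, declared_counts = NULL,
                          mol_type = "SMALL", charge_method = "GASTEIGER",
                          dialect = c("dot", "comma"), repairs = character()) {
  stopifnot(inherits(molecule, "molecule"))
  dialect <- match.arg(dialect)
  if (is.null(declared_counts)) {
    declared_counts <- c(n_atoms(molecule), n_bonds(molecule), 0L, 0L, 0L)
  }
  declared_counts <- as.integer(declared_counts)
  length(declared_counts) <- 5
  declared_counts[is.na(declared_counts)] <- 0L
  names(declared_counts) <- c("n_atoms", "n_bonds", "n_subst", "n_feat",
                              "n_sets")
  structure(list(molecule = molecule, declared_counts = declared_counts,
                 mol_type = mol_type, charge_method = charge_method,
                 dialect = dialect, repairs = repairs),
            class = "mol2_document")
}

#' @export
print.mol2_document <- function(x, ...) {
  cat(sprintf("<mol2_document> %s: %d atoms, %d bonds, dialect=%s",
              x$molecule$name, n_atoms(x$molecule), n_bonds(x$molecule),
              x$dialect))
  if (length(x$repairs)) cat(sprintf(", %d repair(s)", length(x$repairs)))
  cat("\n")
  invisible(x)
}

#' Parse a numeric token in a given decimal dialect
#'
#' In the comma dialect the decimal separator \code{","} is mapped to
#' \code{"."}; the dot dialect passes through. A token containing both
#' separators, or anything non-numeric, is rejected.
#'
#' @param token non-empty character scalar.
#' @param dialect \code{"dot"} or \code{"comma"}.
#' @param context optional string naming the line, used in error messages.
#' @return finite numeric scalar.
#' @export
normalize_decimal <- function(token, dialect = c("dot", "comma"),
                              context = NULL) {
  dialect <- match.arg(dialect)
  where <- if (is.null(context)) "" else paste0(" (", context, ")")
  if (!is.character(token) || length(token) != 1 || !nzchar(token)) {
    stop("malformed number: empty token", where)
  }
  if (grepl(",", token, fixed = TRUE) && grepl(".", token, fixed = TRUE)) {
    stop("malformed number '", token, "': both ',' and '.' present", where)
  }
  s <- if (dialect == "comma") gsub(",", ".", token, fixed = TRUE) else token
  if (!grepl("^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?$", s)) {
    stop("malformed number '", token, "'", where)
  }
  v <- suppressWarnings(as.numeric(s))
  if (!is.finite(v)) stop("malformed number '", token, "'", where)
  v
}

# split one mol2 text into named sections of non-blank content lines,
# keeping the original line numbers for error messages
.mol2_sections <- function(text) {
  lines <- unlist(strsplit(text, "\r\n|\n|\r"))
  marker <- grepl("^@<TRIPOS>", lines)
  sec_name <- sub("^@<TRIPOS>", "", trimws(lines))
  out <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    if (marker[i]) {
      cur <- sec_name[i]
      if (is.null(out[[cur]])) {
        out[[cur]] <- data.frame(lineno = integer(), text = character(),
                                 stringsAsFactors = FALSE)
      }
    } else if (!is.null(cur) && nzchar(trimws(lines[i]))) {
      out[[cur]] <- rbind(out[[cur]],
                          data.frame(lineno = i, text = trimws(lines[i]),
                                     stringsAsFactors = FALSE))
    }
  }
  out
}

#' Parse TRIPOS mol2 text
#'
#' Reads the \code{MOLECULE}, \code{ATOM} and \code{BOND} sections into a
#' \code{\link{mol2_document}}; other sections are skipped with a note. The
#' decimal dialect is auto-detected: any coordinate token containing
#' \code{","} switches the whole file to the comma dialect.
#'
#' In lenient mode, recoverable defects are repaired and logged in the
#' document's \code{repairs}: a 3-token bond record whose trailing token
#' can be re-split into an in-range atom index plus a valid order token is
#' repaired that way (the one defect the builder's own exports show);
#' otherwise unusable bond records are dropped; count mismatches are noted.
#' In strict mode every such defect raises an error naming the line.
#'
#' @param text mol2 content as a single string (or character vector of
#'   lines).
#' @param mode \code{"lenient"} (default) or \code{"strict"}.
#' @return a \code{\link{mol2_document}}.
#' @export
parse_mol2 <- function(text, mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  strict <- mode == "strict"
  if (length(text) > 1) text <- paste(text, collapse = "\n")
  secs <- .mol2_sections(text)
  if (!"MOLECULE" %in% names(secs)) {
    stop("no @<TRIPOS>MOLECULE section found")
  }
  if (!"ATOM" %in% names(secs)) stop("no atoms: missing @<TRIPOS>ATOM section")
  repairs <- character()
  note <- function(msg) repairs <<- c(repairs, msg)

  extra <- setdiff(names(secs), c("MOLECULE", "ATOM", "BOND"))
  for (s in extra) note(sprintf("skipped unsupported section @<TRIPOS>%s", s))

  mol_lines <- secs$MOLECULE$text
  mol_name <- if (length(mol_lines) >= 1) mol_lines[1] else ""
  counts <- c(0L, 0L, 0L, 0L, 0L)
  if (length(mol_lines) >= 2) {
    ctoks <- strsplit(mol_lines[2], "[ \t]+")[[1]]
    cvals <- suppressWarnings(as.integer(ctoks))
    if (anyNA(cvals)) {
      if (strict) stop("malformed counts line: '", mol_lines[2], "'")
      note(sprintf("unparseable counts line '%s'; using actual counts",
                   mol_lines[2]))
      cvals <- NA_integer_
    }
    if (!anyNA(cvals)) {
      counts[seq_along(cvals)[seq_along(cvals) <= 5]] <-
        cvals[seq_len(min(5, length(cvals)))]
    }
  } else if (strict) {
    stop("MOLECULE section lacks a counts line")
  }
  mol_type <- if (length(mol_lines) >= 3) mol_lines[3] else "SMALL"
  charge_method <- if (length(mol_lines) >= 4) mol_lines[4] else "GASTEIGER"

  atom_rows <- if (is.null(secs$ATOM)) {
    data.frame(lineno = integer(), text = character())
  } else {
    secs$ATOM
  }

  # dialect detection over coordinate tokens
  dialect <- "dot"
  for (i in seq_len(nrow(atom_rows))) {
    toks <- strsplit(atom_rows$text[i], "[ \t]+")[[1]]
    if (length(toks) >= 5 && any(grepl(",", toks[3:5], fixed = TRUE))) {
      dialect <- "comma"
      break
    }
  }

  atoms <- list()
  for (i in seq_len(nrow(atom_rows))) {
    ln <- atom_rows$lineno[i]
    toks <- strsplit(atom_rows$text[i], "[ \t]+")[[1]]
    ctx <- sprintf("ATOM record, line %d", ln)
    if (length(toks) < 6) {
      if (strict) stop("malformed ATOM record (", length(toks),
                       " tokens) at line ", ln)
      note(sprintf("dropped malformed ATOM record at line %d", ln))
      next
    }
    idx <- suppressWarnings(as.integer(toks[1]))
    if (is.na(idx)) stop("malformed atom index '", toks[1], "' (", ctx, ")")
    xyz <- vapply(toks[3:5], normalize_decimal, numeric(1),
                  dialect = dialect, context = ctx)
    charge <- NA_real_
    if (length(toks) >= 9) {
      charge <- tryCatch(normalize_decimal(toks[9], dialect, ctx),
                         error = function(e) NA_real_)
    }
    atoms[[length(atoms) + 1]] <- data.frame(
      index = idx, name = toks[2], x = xyz[1], y = xyz[2], z = xyz[3],
      sybyl_type = toks[6],
      subst_id = if (length(toks) >= 7)
        suppressWarnings(as.integer(toks[7])) else 1L,
      subst_name = if (length(toks) >= 8) toks[8] else "N1",
      charge = charge, stringsAsFactors = FALSE)
  }
  atoms <- if (length(atoms)) do.call(rbind, atoms) else
    data.frame(index = integer(), name = character(), x = numeric(),
               y = numeric(), z = numeric(), sybyl_type = character(),
               subst_id = integer(), subst_name = character(),
               charge = numeric(), stringsAsFactors = FALSE)
  atom_ids <- atoms$index

  bond_rows <- if (is.null(secs$BOND)) {
    data.frame(lineno = integer(), text = character())
  } else {
    secs$BOND
  }
  bonds <- list()
  seen_pairs <- character()
  for (i in seq_len(nrow(bond_rows))) {
    ln <- bond_rows$lineno[i]
    toks <- strsplit(bond_rows$text[i], "[ \t]+")[[1]]
    if (length(toks) == 3) {
      # possibly a fused trailing token ("7 3 11" for "7 3 1 1"):
      # try every split of the last token into index + order
      fixed <- NULL
      last <- toks[3]
      if (nchar(last) >= 2) {
        for (cut in seq_len(nchar(last) - 1)) {
          p1 <- substr(last, 1, cut)
          p2 <- substr(last, cut + 1, nchar(last))
          idx <- suppressWarnings(as.integer(p1))
          if (!is.na(idx) && idx %in% atom_ids &&
              p2 %in% .MOL2_ORDER_TOKENS) {
            fixed <- c(toks[1:2], p1, p2)
            break
          }
        }
      }
      if (is.null(fixed)) {
        if (strict) stop("malformed BOND record at line ", ln, ": '",
                         bond_rows$text[i], "'")
        note(sprintf("dropped unrepairable BOND record at line %d: '%s'",
                     ln, bond_rows$text[i]))
        next
      }
      if (strict) stop("malformed BOND record at line ", ln, ": '",
                       bond_rows$text[i], "' (3 tokens)")
      note(sprintf(
        "line %d: re-split trailing bond token '%s' into '%s %s'",
        ln, last, fixed[3], fixed[4]))
      toks <- fixed
    }
    if (length(toks) != 4) {
      if (strict) stop("malformed BOND record at line ", ln, ": '",
                       bond_rows$text[i], "'")
      note(sprintf("dropped malformed BOND record at line %d", ln))
      next
    }
    ab <- suppressWarnings(as.integer(toks[2:3]))
    ord <- toks[4]
    bad <- anyNA(ab) || !all(ab %in% atom_ids) || ab[1] == ab[2] ||
      !ord %in% .MOL2_ORDER_TOKENS
    if (bad) {
      if (strict) {
        stop("invalid BOND record at line ", ln, ": '",
             bond_rows$text[i], "'")
      }
      note(sprintf("dropped invalid BOND record at line %d: '%s'",
                   ln, bond_rows$text[i]))
      next
    }
    key <- paste(min(ab), max(ab))
    if (key %in% seen_pairs) {
      if (strict) stop("duplicate bond at line ", ln, ": '",
                       bond_rows$text[i], "'")
      note(sprintf("dropped duplicate BOND record at line %d", ln))
      next
    }
    seen_pairs <- c(seen_pairs, key)
    bonds[[length(bonds) + 1]] <- data.frame(
      bond_id = length(bonds) + 1L, a = ab[1], b = ab[2],
      order = .normalize_order_token(ord), stringsAsFactors = FALSE)
  }
  bonds <- if (length(bonds)) do.call(rbind, bonds) else NULL

  mol <- molecule(mol_name, atoms, bonds)

  if (counts[1] != n_atoms(mol) || counts[2] != n_bonds(mol)) {
    msg <- sprintf(
      "declared counts (%d atoms, %d bonds) differ from parsed (%d, %d)",
      counts[1], counts[2], n_atoms(mol), n_bonds(mol))
    if (strict) stop(msg)
    note(msg)
  }
  mol2_document(mol, declared_counts = counts, mol_type = mol_type,
                charge_method = charge_method, dialect = dialect,
                repairs = repairs)
}

#' Read a mol2 file
#' @param path file path (UTF-8; LF or CRLF line endings).
#' @param mode \code{"lenient"} or \code{"strict"}; see
#'   \code{\link{parse_mol2}}.
#' @return a \code{\link{mol2_document}}.
#' @export
read_mol2 <- function(path, mode = c("lenient", "strict")) {
  if (!file.exists(path)) stop("file not found: ", path)
  parse_mol2(paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                   collapse = "\n"),
             mode = match.arg(mode))
}

#' Serialize a mol2 document to text
#'
#' Sections are written in the order MOLECULE, ATOM, BOND; counts reflect
#' the actual molecule. Coordinates are printed with at least three
#' decimals so a written file re-parses to the identical graph and
#' coordinates.
#'
#' @param doc a \code{\link{mol2_document}}.
#' @param dialect output decimal dialect; defaults to the document's own.
#' @return a single string (ends with a newline).
#' @export
write_mol2 <- function(doc, dialect = NULL) {
  stopifnot(inherits(doc, "mol2_document"))
  if (is.null(dialect)) dialect <- doc$dialect
  dialect <- match.arg(dialect, c("dot", "comma"))
  mol <- doc$molecule
  dec <- function(s) {
    if (dialect == "comma") gsub(".", ",", s, fixed = TRUE) else s
  }
  lines <- c(
    "@<TRIPOS>MOLECULE",
    mol$name,
    paste(c(n_atoms(mol), n_bonds(mol), doc$declared_counts[3:5]),
          collapse = " "),
    doc$mol_type,
    doc$charge_method,
    "@<TRIPOS>ATOM")
  for (i in seq_len(n_atoms(mol))) {
    a <- mol$atoms[i, ]
    fields <- c(a$index, a$name, dec(fmt_num(c(a$x, a$y, a$z))),
                a$sybyl_type, a$subst_id, a$subst_name)
    if (!is.na(a$charge)) fields <- c(fields, dec(fmt_num(a$charge, 4)))
    lines <- c(lines, paste(fields, collapse = " "))
  }
  lines <- c(lines, "@<TRIPOS>BOND")
  for (k in seq_len(n_bonds(mol))) {
    b <- mol$bonds[k, ]
    lines <- c(lines, paste(b$bond_id, b$a, b$b, b$order))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write a mol2 document to a file
#' @inheritParams write_mol2
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_mol2_file <- function(doc, path, dialect = NULL) {
  writeLines(sub("\n$", "", write_mol2(doc, dialect)), path, useBytes = TRUE)
  invisible(path)
}
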