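# Builder-side chemistry operations as library functions: bond
# feasibility (the green/red display), bond-order editing, hydrogen
# balancing, and harmonic bond-length minimization.

#' Equilibrium bond-length table
#'
#' Equilibrium lengths r0 per unordered element pair (Angstrom), defaults
#' from summed single-bond covalent radii (C-C 1.54, C-H 1.09, O-H 0.96,
#' ...), plus one global harmonic force constant k. Loaded from a shipped
#' key-value config file; pass a path to override.
#'
#' @param path optional config file: lines of \code{"<el1> <el2> <r0>"};
#'   a line \code{"k <value>"} sets the force constant. \code{#} comments.
#' @param k force constant override (energy/Angstrom^2 units; the absolute
#'   scale only rescales gradients, it does not move the minimum).
#' @return object of class \code{"bond_length_table"}.
#' @export
bond_length_table <- function(path = NULL, k = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bond_lengths.conf",
                        package = "mol2narupa")
  }
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  r0 <- numeric()
  kval <- 1
  for (ln in lines) {
    toks <- strsplit(ln, "[ \t]+")[[1]]
    if (length(toks) == 2 && toks[1] == "k") {
      kval <- as.numeric(toks[2])
    } else if (length(toks) == 3) {
      v <- as.numeric(toks[3])
      if (!is.finite(v) || v <= 0) {
        stop("invalid bond length in '", ln, "'")
      }
      r0[[.pair_key(toks[1], toks[2])]] <- v
    } else {
      stop("malformed bond-length line: '", ln, "'")
    }
  }
  if (!is.null(k)) kval <- as.numeric(k)
  if (!is.finite(kval) || kval <= 0) stop("force constant must be > 0")
  structure(list(r0 = r0, k = kval), class = "bond_length_table")
}

.pair_key <- function(e1, e2) paste(sort(c(e1, e2)), collapse = "-")

#' Look up an equilibrium bond length
#' @param table a \code{\link{bond_length_table}}.
#' @param e1,e2 element symbols (order irrelevant).
#' @return length in Angstrom.
#' @export
r0_lookup <- function(table, e1, e2) {
  key <- .pair_key(e1, e2)
  if (!key %in% names(table$r0)) {
    stop("no equilibrium length for element pair ", key)
  }
  table$r0[[key]]
}

#' Can a bond be created?
#'
#' Library analogue of the builder's green/red bond preview: a proposed
#' bond between atoms \code{i} and \code{j} with the given order is
#' feasible iff no bond already joins the pair and adding the order's
#' valence weight keeps both atoms within their element's maximum valence.
#'
#' @param mol a \code{molecule}.
#' @param i,j distinct existing atom indices.
#' @param order proposed bond order (default \code{"1"}).
#' @param model a \code{\link{valence_model}}.
#' @return list with \code{feasible} (logical) and \code{reason}
#'   (\code{NULL} when feasible, otherwise a string).
#' @export
bond_feasible <- function(mol, i, j, order = "1",
                          model = valence_model()) {
  order <- as.character(order)
  for (idx in c(i, j)) {
    if (!idx %in% mol$atoms$index) stop("no such atom: ", idx)
  }
  if (i == j) {
    return(list(feasible = FALSE, reason = "an atom cannot bond to itself"))
  }
  exists <- any((mol$bonds$a == i & mol$bonds$b == j) |
                  (mol$bonds$a == j & mol$bonds$b == i))
  if (exists) {
    return(list(feasible = FALSE,
                reason = sprintf("bond %d-%d already exists", i, j)))
  }
  w <- bond_order_value(order)
  sums <- valence_sums(mol)
  for (idx in c(i, j)) {
    el <- mol$atoms$element[idx]
    mx <- max_valence_of(model, el)
    if (sums[idx] + w > mx + 1e-9) {
      return(list(feasible = FALSE, reason = sprintf(
        "atom %d (%s): valence %.1f + %.1f would exceed maximum %d",
        idx, mol$atoms$name[idx], sums[idx], w, mx)))
    }
  }
  list(feasible = TRUE, reason = NULL)
}

#' Add a bond
#'
#' Adds a bond after checking \code{\link{bond_feasible}}; refuses with the
#' feasibility reason otherwise.
#'
#' @inheritParams bond_feasible
#' @return the modified \code{molecule}.
#' @export
add_bond <- function(mol, i, j, order = "1", model = valence_model()) {
  f <- bond_feasible(mol, i, j, order, model)
  if (!f$feasible) stop("cannot add bond ", i, "-", j, ": ", f$reason)
  bonds <- rbind(mol$bonds,
                 data.frame(bond_id = n_bonds(mol) + 1L, a = i, b = j,
                            order = as.character(order),
                            stringsAsFactors = FALSE))
  molecule(mol$name, mol$atoms, bonds)
}

#' Change the order of an existing bond
#'
#' Replaces the order of bond \code{(i, j)} and revalidates; the edit is
#' refused (with the offending atom named) when the new order would push
#' either endpoint past its maximum valence.
#'
#' @param mol a \code{molecule}.
#' @param i,j endpoints of an existing bond.
#' @param order new bond order.
#' @param model a \code{\link{valence_model}}.
#' @return the modified \code{molecule}.
#' @export
set_bond_order <- function(mol, i, j, order, model = valence_model()) {
  order <- as.character(order)
  hit <- which((mol$bonds$a == i & mol$bonds$b == j) |
                 (mol$bonds$a == j & mol$bonds$b == i))
  if (length(hit) != 1) stop("no such bond: ", i, "-", j)
  if (identical(mol$bonds$order[hit], order)) return(mol)
  old_w <- bond_order_value(mol$bonds$order[hit])
  new_w <- bond_order_value(order)
  sums <- valence_sums(mol)
  for (idx in c(i, j)) {
    el <- mol$atoms$element[idx]
    mx <- max_valence_of(model, el)
    if (sums[idx] - old_w + new_w > mx + 1e-9) {
      stop(sprintf(
        "cannot set bond %d-%d to order %s: atom %d (%s) would have valence %.1f > %d",
        i, j, order, idx, mol$atoms$name[idx],
        sums[idx] - old_w + new_w, mx))
    }
  }
  mol$bonds$order[hit] <- order
  molecule(mol$name, mol$atoms, mol$bonds)
}

#' Balance hydrogens
#'
#' Brings every non-hydrogen atom's valence sum up to exactly its maximum
#' valence by adding or removing hydrogens only; bonds between heavy atoms
#' are never altered. Added hydrogens get fresh indices and names
#' \code{"Hk"}, single bonds, and positions on a sphere of the
#' element-to-H table length around their heavy atom, with directions from
#' a deterministic seeded generator so results are reproducible. When an
#' atom is over its maximum, its highest-index hydrogens are removed first;
#' if it is still over valence with no hydrogens left, that is an error
#' naming the atom.
#'
#' The operation is idempotent: applying it twice equals applying it once.
#'
#' @param mol a \code{molecule}.
#' @param model a \code{\link{valence_model}}.
#' @param table a \code{\link{bond_length_table}} (for the H distance).
#' @param seed integer seed for the placement directions (default 0).
#' @return the balanced \code{molecule}.
#' @export
balance_hydrogens <- function(mol, model = valence_model(),
                              table = bond_length_table(), seed = 0) {
  stopifnot(inherits(mol, "molecule"))
  # pass 1: remove excess hydrogens (highest atom index first)
  repeat {
    sums <- valence_sums(mol)
    over <- which(mol$atoms$element != "H" &
                    sums > model$max_valence[mol$atoms$element] + 1e-9)
    if (!length(over)) break
    i <- over[1]
    h_nb <- integer()
    for (k in seq_len(n_bonds(mol))) {
      a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
      if (a == i && mol$atoms$element[b] == "H") h_nb <- c(h_nb, b)
      if (b == i && mol$atoms$element[a] == "H") h_nb <- c(h_nb, a)
    }
    if (!length(h_nb)) {
      stop(sprintf(
        "atom %d (%s) has valence %.1f > %d and no hydrogens to remove",
        i, mol$atoms$name[i], sums[i],
        max_valence_of(model, mol$atoms$element[i])))
    }
    drop <- max(h_nb)
    keep <- mol$atoms$index != drop
    bonds <- mol$bonds[mol$bonds$a != drop & mol$bonds$b != drop, ,
                       drop = FALSE]
    mol <- molecule(mol$name, mol$atoms[keep, , drop = FALSE], bonds)
  }
  # pass 2: add missing hydrogens, heavy atoms in index order
  gen <- lcg_new(seed)
  sums <- valence_sums(mol)
  heavy <- which(mol$atoms$element != "H")
  n_existing_h <- sum(mol$atoms$element == "H")
  h_counter <- n_existing_h
  atoms <- mol$atoms
  bonds <- mol$bonds
  next_idx <- n_atoms(mol)
  for (i in heavy) {
    el <- atoms$element[i]
    deficit <- max_valence_of(model, el) - sums[i]
    if (deficit < 1 - 1e-9) next
    d <- r0_lookup(table, el, "H")
    center <- as.numeric(atoms[i, c("x", "y", "z")])
    for (m in seq_len(floor(deficit + 1e-9))) {
      h_counter <- h_counter + 1
      next_idx <- next_idx + 1L
      pos <- center + d * lcg_unit_vector(gen)
      atoms <- rbind(atoms, data.frame(
        index = next_idx, name = paste0("H", h_counter),
        x = pos[1], y = pos[2], z = pos[3], sybyl_type = "H",
        element = "H", subst_id = atoms$subst_id[i],
        subst_name = atoms$subst_name[i], charge = NA_real_,
        stringsAsFactors = FALSE))
      bonds <- rbind(bonds, data.frame(
        bond_id = nrow(bonds) + 1L, a = i, b = next_idx, order = "1",
        stringsAsFactors = FALSE))
    }
  }
  molecule(mol$name, atoms, bonds)
}

.bond_energy <- function(coords, bonds, r0s, k) {
  e <- 0
  for (m in seq_len(nrow(bonds))) {
    d <- euclid(coords[bonds$a[m], ], coords[bonds$b[m], ])
    e <- e + k * (d - r0s[m])^2
  }
  e
}

.bond_gradient <- function(coords, bonds, r0s, k) {
  g <- matrix(0, nrow(coords), 3)
  for (m in seq_len(nrow(bonds))) {
    a <- bonds$a[m]; b <- bonds$b[m]
    dv <- coords[a, ] - coords[b, ]
    d <- sqrt(sum(dv^2))
    if (d < 1e-12) next  # coincident atoms: no defined direction
    gcom <- 2 * k * (d - r0s[m]) * dv / d
    g[a, ] <- g[a, ] + gcom
    g[b, ] <- g[b, ] - gcom
  }
  g
}

#' Harmonic bond-length minimization
#'
#' Gradient descent on the bond-term energy
#' \deqn{E = \sum_{(a,b)} k \, (d_{ab} - r^0_{ab})^2}
#' where \eqn{d_{ab}} is the current bond length and \eqn{r^0_{ab}} the
#' table's equilibrium length for the element pair. Angles and torsions
#' are unconstrained: only bond lengths are adjusted, mirroring the
#' builder's "minimize" action. The descent uses a fixed nominal step,
#' halved within an iteration whenever a step would increase the energy,
#' so the returned energy trace is always non-increasing. Iteration stops
#' when the largest per-atom gradient norm drops below \code{tol} or
#' after \code{max_steps} iterations.
#'
#' @param mol a \code{molecule} (must validate cleanly).
#' @param table a \code{\link{bond_length_table}}; a bond whose element
#'   pair is absent from the table is an error naming the pair.
#' @param max_steps maximum iterations (default 2000).
#' @param step_size nominal step length multiplier (> 0, default 0.02).
#' @param tol gradient-norm stopping threshold (default 1e-4).
#' @return list with \code{molecule} (relaxed coordinates),
#'   \code{trace} (energy per iteration, element 1 the initial energy),
#'   and \code{converged} (logical).
#' @export
minimize_bonds <- function(mol, table = bond_length_table(),
                           max_steps = 2000, step_size = 0.02, tol = 1e-4) {
  stopifnot(inherits(mol, "molecule"), step_size > 0)
  bonds <- mol$bonds
  coords <- as.matrix(mol$atoms[, c("x", "y", "z")])
  if (nrow(bonds) == 0) {
    return(list(molecule = mol, trace = 0, converged = TRUE))
  }
  r0s <- vapply(seq_len(nrow(bonds)), function(m) {
    r0_lookup(table, mol$atoms$element[bonds$a[m]],
              mol$atoms$element[bonds$b[m]])
  }, numeric(1))
  k <- table$k
  e <- .bond_energy(coords, bonds, r0s, k)
  trace <- e
  converged <- FALSE
  for (it in seq_len(max_steps)) {
    g <- .bond_gradient(coords, bonds, r0s, k)
    gmax <- sqrt(max(rowSums(g^2)))
    if (gmax < tol) {
      converged <- TRUE
      break
    }
    step <- step_size
    repeat {
      cand <- coords - step * g
      e_new <- .bond_energy(cand, bonds, r0s, k)
      if (e_new <= e || step < 1e-12) break
      step <- step / 2
    }
    if (e_new > e) break  # no descent possible at any step length
    coords <- cand
    e <- e_new
    trace <- c(trace, e)
  }
  mol$atoms$x <- coords[, 1]
  mol$atoms$y <- coords[, 2]
  mol$atoms$z <- coords[, 3]
  list(molecule = molecule(mol$name, mol$atoms, mol$bonds),
       trace = trace, converged = converged)
}
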