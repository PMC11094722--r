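#' Read a PDBQT ligand file
#'
#' Parses ATOM/HETATM records (coordinates, partial charge, AutoDock atom
#' type) and the ROOT/BRANCH torsion tree. Both flexible (torsion-tree) and
#' flat rigid files are accepted. PDBQT carries no bond block, so the
#' returned molecule has an empty bond table; its torsion tree (rotatable
#' atom pairs and the atom sets they move) is reconstructed from the BRANCH
#' nesting.
#'
#' @param path Path to a PDBQT file.
#' @return A prepared `lig_molecule`.
#' @export
read_pdbqt <- function(path) {
  if (!file.exists(path)) abort(sprintf("PDBQT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  serial <- integer(); xs <- ys <- zs <- qs <- numeric()
  types <- character()
  torsion_pairs <- list()   # (parent serial, child serial)
  branch_stack <- list()    # each: list(i, j, members = serials)
  closed <- list()
  name <- "ligand"
  for (ln in lines) {
    rec <- substr(ln, 1, 6)
    if (rec %in% c("ATOM  ", "HETATM")) {
      s <- as.integer(substr(ln, 7, 11))
      x <- as.numeric(substr(ln, 31, 38))
      y <- as.numeric(substr(ln, 39, 46))
      z <- as.numeric(substr(ln, 47, 54))
      rest <- strsplit(trimws(substr(ln, 55, nchar(ln))), "\\s+")[[1]]
      if (length(rest) < 4) {
        abort(sprintf("malformed PDBQT ATOM line (need occ/temp/charge/type): %s", ln))
      }
      q <- as.numeric(rest[3]); ty <- rest[4]
      if (is.na(q) || is.na(ty)) abort(sprintf("bad charge/type in: %s", ln))
      serial <- c(serial, s); xs <- c(xs, x); ys <- c(ys, y); zs <- c(zs, z)
      qs <- c(qs, q); types <- c(types, ty)
      if (length(branch_stack)) {
        for (d in seq_along(branch_stack)) {
          branch_stack[[d]]$members <- c(branch_stack[[d]]$members, s)
        }
      }
    } else if (startsWith(ln, "BRANCH")) {
      ij <- as.integer(strsplit(trimws(sub("^BRANCH", "", ln)), "\\s+")[[1]])
      branch_stack[[length(branch_stack) + 1L]] <-
        list(i = ij[1], j = ij[2], members = integer())
    } else if (startsWith(ln, "ENDBRANCH")) {
      if (!length(branch_stack)) abort("unbalanced ENDBRANCH in PDBQT")
      closed[[length(closed) + 1L]] <- branch_stack[[length(branch_stack)]]
      branch_stack[[length(branch_stack)]] <- NULL
    } else if (startsWith(ln, "REMARK  Name =")) {
      name <- trimws(sub("REMARK  Name =", "", ln))
    }
  }
  if (length(branch_stack)) abort("unbalanced BRANCH in PDBQT")
  if (!length(serial)) abort(sprintf("no ATOM records in %s", path))
  idx_of <- setNames(seq_along(serial), serial)
  atoms <- tibble(
    element = ad_type_element(types),
    x = xs, y = ys, z = zs, charge = qs, ad_type = types,
    is_polar_h = types %in% c("HD", "HS")
  )
  torsions <- tibble(
    i = vapply(closed, function(b) unname(idx_of[as.character(b$i)]), integer(1)),
    j = vapply(closed, function(b) unname(idx_of[as.character(b$j)]), integer(1)),
    moving = lapply(closed, function(b) unname(idx_of[as.character(b$members)]))
  )
  new_molecule(name, atoms, bonds = NULL, torsions = torsions,
               prepared = TRUE, rigid = nrow(torsions) == 0L)
}

#' Write a molecule as PDBQT
#'
#' Emits AutoDock-convention PDBQT: ATOM records carrying the Gasteiger
#' partial charge and atom type, and for flexible molecules a nested
#' ROOT/BRANCH torsion tree with a final TORSDOF count. Rigid molecules are
#' written as a single ROOT block with TORSDOF 0.
#'
#' @param mol A prepared `lig_molecule` (atom types assigned).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdbqt <- function(mol, path) {
  if (any(is.na(mol$atoms$ad_type))) {
    abort("molecule has atoms without an AutoDock atom type; run prepare_ligand() first")
  }
  n <- nrow(mol$atoms)
  tor <- if (mol$rigid) mol$torsions[0, ] else mol$torsions
  k <- nrow(tor)

  # partition atoms into rigid fragments by deleting the rotatable bonds
  frag_id <- integer(n)
  if (k > 0) {
    cut <- matrix(c(tor$i, tor$j), ncol = 2)
    adj <- vector("list", n)
    for (b in seq_len(nrow(mol$bonds))) {
      bi <- mol$bonds$i[b]; bj <- mol$bonds$j[b]
      if (any(cut[, 1] == bi & cut[, 2] == bj) ||
          any(cut[, 1] == bj & cut[, 2] == bi)) next
      adj[[bi]] <- c(adj[[bi]], bj); adj[[bj]] <- c(adj[[bj]], bi)
    }
    fid <- 0L
    for (s in seq_len(n)) {
      if (frag_id[s] > 0L) next
      fid <- fid + 1L
      stack <- s; frag_id[s] <- fid
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        for (w in adj[[v]]) if (frag_id[w] == 0L) {
          frag_id[w] <- fid; stack <- c(stack, w)
        }
      }
    }
  } else {
    frag_id[] <- 1L
  }
  frags <- split(seq_len(n), frag_id)
  sizes <- lengths(frags)
  root_frag <- as.integer(names(frags)[which.max(sizes)])

  serial_of <- integer(n)
  counter <- new.env()
  counter$s <- 0L
  counter$lines <- character()

  atom_line <- function(a) {
    counter$s <- counter$s + 1L
    serial_of[a] <<- counter$s
    at <- mol$atoms[a, ]
    sprintf("ATOM  %5d %-4s%-3s %5d    %8.3f%8.3f%8.3f%6.2f%6.2f    %+6.3f %-2s",
            counter$s, substr(at$element, 1, 4), "UNL", 1L,
            at$x, at$y, at$z, 0, 0, at$charge, at$ad_type)
  }
  emit <- function(...) counter$lines <- c(counter$lines, ...)

  # branches leaving fragment f, excluding the one we arrived through
  frag_branches <- function(f, via) {
    out <- list()
    if (k == 0) return(out)
    for (t in seq_len(k)) {
      if (!is.null(via) && t == via) next
      fi <- frag_id[tor$i[t]]; fj <- frag_id[tor$j[t]]
      if (fi == f) out[[length(out) + 1L]] <- list(t = t, a = tor$i[t], b = tor$j[t])
      else if (fj == f) out[[length(out) + 1L]] <- list(t = t, a = tor$j[t], b = tor$i[t])
    }
    out
  }

  write_frag <- function(f, via, first_atom) {
    members <- frags[[as.character(f)]]
    if (!is.null(first_atom)) members <- c(first_atom, setdiff(members, first_atom))
    for (a in members) emit(atom_line(a))
    for (br in frag_branches(f, via)) {
      child_serial_a <- serial_of[br$a]
      # child atom serial is the next one assigned
      emit(sprintf("BRANCH %3d %3d", child_serial_a, counter$s + 1L))
      write_frag(frag_id[br$b], br$t, br$b)
      emit(sprintf("ENDBRANCH %3d %3d", child_serial_a, serial_of[br$b]))
    }
  }

  emit(sprintf("REMARK  Name = %s", mol$name))
  emit("ROOT")
  # root atoms first, then close ROOT before branching out
  members <- frags[[as.character(root_frag)]]
  for (a in members) emit(atom_line(a))
  emit("ENDROOT")
  for (br in frag_branches(root_frag, NULL)) {
    emit(sprintf("BRANCH %3d %3d", serial_of[br$a], counter$s + 1L))
    write_frag(frag_id[br$b], br$t, br$b)
    emit(sprintf("ENDBRANCH %3d %3d", serial_of[br$a], serial_of[br$b]))
  }
  emit(sprintf("TORSDOF %d", k))
  writeLines(counter$lines, path)
  invisible(path)
}
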