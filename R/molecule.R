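#' Parsed molecule objects
#'
#' A `csgl_molecule` is the heavy-atom graph of one molecule: an atom table
#' (element, formal charge, attached hydrogen count, ring membership), a bond
#' table with 1-based atom indices and a bond-order tag (`"1"`, `"2"`, `"3"`,
#' `"ar"`), the ring count (size of the smallest set of smallest rings, i.e.
#' the cycle-space dimension of the bond graph), and a canonical SMILES
#' identity shared by every input describing the same molecule.
#'
#' @name csgl_molecule
NULL

# default valences used for implicit hydrogen assignment (heavy-atom graph)
.valences <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

#' Canonicalize a SMILES string
#'
#' Converts any valid SMILES to OpenBabel's canonical form, which is the
#' molecule identity used throughout the package. Invalid input yields an
#' error naming the offending string.
#'
#' @param smiles a single SMILES string.
#' @return the canonical SMILES string.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(trimws(smiles))) {
    stop("cannot parse empty SMILES string", call. = FALSE)
  }
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = smiles),
    error = function(e) ""
  )
  out <- sub("\t.*$", "", trimws(out))
  if (!nzchar(out)) {
    stop(sprintf("unparsable SMILES: '%s'", smiles), call. = FALSE)
  }
  out
}

# --- canonical-SMILES tokenizer -------------------------------------------
# Parses the constrained grammar OpenBabel emits for canonical SMILES:
# organic-subset and bracket atoms, explicit bonds - = # : / \, branches,
# ring-closure digits and %nn, dot-separated components. Stereo marks and
# isotopes are accepted and ignored.

.parse_bracket_atom <- function(token, where) {
  m <- regmatches(token, regexec(
    "^\\[([0-9]*)(se|as|[bcnops]|[A-Z][a-z]?|\\*)(@{1,2}[A-Z0-9]*)?(H[0-9]*)?(\\+{1,3}[0-9]*|-{1,3}[0-9]*)?(:[0-9]+)?\\]$",
    token
  ))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("unparsable bracket atom '%s' in '%s'", token, where),
         call. = FALSE)
  }
  elem <- m[3]
  aromatic <- elem %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  htok <- m[5]
  hcount <- if (!nzchar(htok)) 0L
            else if (htok == "H") 1L
            else as.integer(sub("^H", "", htok))
  ctok <- m[6]
  charge <- 0L
  if (nzchar(ctok)) {
    sign <- if (substr(ctok, 1, 1) == "+") 1L else -1L
    digits <- gsub("[+-]", "", ctok)
    mag <- if (nzchar(digits)) as.integer(digits)
           else nchar(gsub("[^+-]", "", ctok))
    charge <- sign * mag
  }
  el <- paste0(toupper(substr(elem, 1, 1)), substring(elem, 2))
  if (elem == "*") el <- "*"
  list(element = el, aromatic = aromatic, charge = charge, hcount = hcount)
}

.tokenize_smiles <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  elem <- character(); arom <- logical(); charge <- integer(); hexp <- integer()
  b_a <- integer(); b_b <- integer(); b_ord <- character()
  prev <- NA_integer_
  pending <- ""
  stack <- integer()
  open_rings <- list()
  organic2 <- c("Cl", "Br")
  organic1 <- c("B", "C", "N", "O", "P", "S", "F", "I")
  aromatic1 <- c("b", "c", "n", "o", "p", "s")

  add_atom <- function(el, ar, ch, hx) {
    elem[length(elem) + 1L] <<- el
    arom[length(arom) + 1L] <<- ar
    charge[length(charge) + 1L] <<- ch
    hexp[length(hexp) + 1L] <<- hx
    idx <- length(elem)
    if (!is.na(prev)) {
      b_a[length(b_a) + 1L] <<- prev
      b_b[length(b_b) + 1L] <<- idx
      b_ord[length(b_ord) + 1L] <<- pending
    }
    pending <<- ""
    prev <<- idx
  }
  close_ring <- function(key) {
    if (!is.null(open_rings[[key]])) {
      op <- open_rings[[key]]
      ord <- if (nzchar(pending)) pending else op$bond
      b_a[length(b_a) + 1L] <<- op$atom
      b_b[length(b_b) + 1L] <<- prev
      b_ord[length(b_ord) + 1L] <<- ord
      open_rings[[key]] <<- NULL
    } else {
      open_rings[[key]] <<- list(atom = prev, bond = pending)
    }
    pending <<- ""
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop(sprintf("unbalanced bracket in SMILES '%s'", s), call. = FALSE)
      tok <- paste(chars[i:j], collapse = "")
      at <- .parse_bracket_atom(tok, s)
      add_atom(at$element, at$aromatic, at$charge, at$hcount)
      i <- j + 1L
    } else if (two %in% organic2) {
      add_atom(two, FALSE, 0L, NA_integer_)
      i <- i + 2L
    } else if (ch %in% organic1) {
      add_atom(ch, FALSE, 0L, NA_integer_)
      i <- i + 1L
    } else if (ch %in% aromatic1) {
      add_atom(toupper(ch), TRUE, 0L, NA_integer_)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- switch(ch, "-" = "1", "=" = "2", "#" = "3", ":" = ":", "1")
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending <- ""
      i <- i + 1L
    } else if (ch == "(") {
      stack[length(stack) + 1L] <- prev
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) {
        stop(sprintf("unbalanced parenthesis in SMILES '%s'", s), call. = FALSE)
      }
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop(sprintf("truncated ring closure in '%s'", s), call. = FALSE)
      close_ring(paste(chars[(i + 1L):(i + 2L)], collapse = ""))
      i <- i + 3L
    } else {
      stop(sprintf("unexpected character '%s' in SMILES '%s'", ch, s), call. = FALSE)
    }
  }
  if (length(open_rings) > 0L) {
    stop(sprintf("unmatched ring closure in SMILES '%s'", s), call. = FALSE)
  }
  if (length(elem) == 0L) {
    stop(sprintf("no atoms in SMILES '%s'", s), call. = FALSE)
  }
  list(
    element = elem, aromatic = arom, charge = charge, hexp = hexp,
    bond_a = b_a, bond_b = b_b, bond_ord = b_ord
  )
}

.implicit_h <- function(element, aromatic, bond_orders) {
  # bond_orders: character tags of incident bonds ("1","2","3","ar")
  vs <- .valences[[element]]
  if (is.null(vs)) return(0L)
  ords <- c("1" = 1, "2" = 2, "3" = 3, "ar" = 1)[bond_orders]
  total <- sum(ords)
  # an aromatic C or N carries one formal double bond in any kekule structure
  if (aromatic && element %in% c("C", "N")) total <- total + 1
  fit <- vs[vs >= total]
  if (length(fit) == 0L) return(0L)
  as.integer(fit[1] - total)
}

#' Parse a SMILES string into a molecule
#'
#' Canonicalizes the input with OpenBabel and extracts the heavy-atom graph:
#' atoms with element, formal charge, hydrogen count and ring membership;
#' bonds tagged single/double/triple/aromatic (aromatic systems are kept as
#' aromatic bonds, not kekulized); and the SSSR ring count. Hydrogens are
#' implicit throughout: only heavy-atom bonds are enumerated.
#'
#' @param smiles a single SMILES string.
#' @return a [csgl_molecule] object.
#' @examples
#' m <- parse_molecule("c1ccccc1")
#' m$ring_count       # 1
#' nrow(m$bonds)      # 6 aromatic bonds
#' @export
parse_molecule <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles) || !nzchar(trimws(smiles))) {
    stop("cannot parse empty SMILES string", call. = FALSE)
  }
  hit <- get0(smiles, envir = the$mol_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  can <- canonical_smiles(smiles)
  hit <- get0(can, envir = the$mol_cache, inherits = FALSE)
  if (!is.null(hit)) {
    assign(smiles, hit, envir = the$mol_cache)
    return(hit)
  }
  tk <- .tokenize_smiles(can)
  n_atoms <- length(tk$element)
  n_bonds <- length(tk$bond_a)

  in_ring_bond <- rep(FALSE, n_bonds)
  n_comp <- n_atoms
  if (n_bonds > 0L) {
    g <- igraph::graph_from_edgelist(cbind(tk$bond_a, tk$bond_b), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n_atoms - igraph::vcount(g)))
    n_comp <- igraph::components(g)$no
    br <- as.integer(igraph::bridges(g))
    in_ring_bond <- !(seq_len(n_bonds) %in% br)
  }

  # resolve bond-order tags: implicit bond between two aromatic atoms is
  # aromatic only when it lies in a ring (biphenyl bridges stay single)
  ord <- character(n_bonds)
  for (k in seq_len(n_bonds)) {
    tag <- tk$bond_ord[k]
    both_ar <- tk$aromatic[tk$bond_a[k]] && tk$aromatic[tk$bond_b[k]]
    ord[k] <- if (tag == ":") "ar"
              else if (nzchar(tag)) tag
              else if (both_ar && in_ring_bond[k]) "ar"
              else "1"
  }

  in_ring_atom <- rep(FALSE, n_atoms)
  if (any(in_ring_bond)) {
    in_ring_atom[unique(c(tk$bond_a[in_ring_bond], tk$bond_b[in_ring_bond]))] <- TRUE
  }

  num_h <- integer(n_atoms)
  for (j in seq_len(n_atoms)) {
    if (!is.na(tk$hexp[j])) {
      num_h[j] <- tk$hexp[j]
    } else {
      inc <- ord[tk$bond_a == j | tk$bond_b == j]
      num_h[j] <- .implicit_h(tk$element[j], tk$aromatic[j], inc)
    }
  }

  mol <- structure(
    list(
      canonical_id = can,
      atoms = data.frame(
        element = tk$element,
        formal_charge = tk$charge,
        num_hydrogens = num_h,
        in_ring = in_ring_atom,
        aromatic = tk$aromatic,
        stringsAsFactors = FALSE
      ),
      bonds = data.frame(
        a = tk$bond_a, b = tk$bond_b, order = ord,
        stringsAsFactors = FALSE
      ),
      ring_count = as.integer(n_bonds - n_atoms + n_comp)
    ),
    class = "csgl_molecule"
  )
  if (any(mol$bonds$a == mol$bonds$b)) {
    stop(sprintf("self-bond in parsed molecule '%s'", can), call. = FALSE)
  }
  assign(smiles, mol, envir = the$mol_cache)
  assign(can, mol, envir = the$mol_cache)
  mol
}

#' @export
print.csgl_molecule <- function(x, ...) {
  cat(sprintf(
    "<molecule> %s  (%d atoms, %d bonds, %d rings)\n",
    x$canonical_id, nrow(x$atoms), nrow(x$bonds), x$ring_count
  ))
  invisible(x)
}

#' @export
format.csgl_molecule <- function(x, ...) x$canonical_id

is_molecule <- function(x) inherits(x, "csgl_molecule")
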