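# Minimal SMILES reader for the heavy-atom molecular graphs the attribute
# encoder consumes. Supports the organic-subset atoms C N O S P F Cl Br I,
# branches, ring-closure digits and explicit -, =, # bonds. Hydrogens are
# implicit and never materialised. Aromatic (lowercase) notation, brackets,
# charges and stereo markers are outside the supported grammar and raise a
# parse error naming the offending position.

ATOM_TYPES <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

#' Convert a SMILES string to a molecular graph
#'
#' One node per heavy atom, one undirected edge per bond (ring-closure bonds
#' included). Node features are categorical codes (atom type, degree, formal
#' charge); edge features are the bond order.
#'
#' @param smiles a non-empty SMILES string over the supported grammar.
#' @return an object of class `mol_graph`: list with `n` (atom count),
#'   `atom` (character vector of element symbols), `edges` (m x 2 integer
#'   matrix, 1-based endpoints), `bond_order` (integer vector, 1/2/3),
#'   `charge` (integer vector) and the source `smiles`.
#' @export
smiles_to_graph <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    stop("SMILES must be a single non-empty string")
  }
  chars <- strsplit(smiles, "")[[1]]
  n_chars <- length(chars)
  atom <- character()
  edges <- matrix(integer(), 0L, 2L)
  order <- integer()
  stack <- integer()         # open-branch attachment points
  prev <- 0L                 # index of the previous atom (0 = none)
  pending_bond <- 1L         # order carried by an explicit bond symbol
  rings <- list()            # digit -> c(atom, bond order)

  add_edge <- function(i, j, o) {
    if (i == j) stop("self-bond at position ", pos, " in '", smiles, "'")
    edges <<- rbind(edges, c(min(i, j), max(i, j)))
    order <<- c(order, o)
  }

  pos <- 0L
  while (pos < n_chars) {
    pos <- pos + 1L
    ch <- chars[pos]
    if (ch %in% c("C", "N", "O", "S", "P", "F", "I", "B")) {
      sym <- ch
      # two-letter elements Cl and Br
      if (ch == "C" && pos < n_chars && chars[pos + 1L] == "l") {
        sym <- "Cl"; pos <- pos + 1L
      } else if (ch == "B") {
        if (pos < n_chars && chars[pos + 1L] == "r") {
          sym <- "Br"; pos <- pos + 1L
        } else {
          stop("unsupported atom 'B' at position ", pos, " in '", smiles, "'")
        }
      }
      atom <- c(atom, sym)
      idx <- length(atom)
      if (prev > 0L) add_edge(prev, idx, pending_bond)
      prev <- idx
      pending_bond <- 1L
    } else if (ch %in% c("-", "=", "#")) {
      pending_bond <- match(ch, c("-", "=", "#"))
    } else if (ch == "(") {
      if (prev == 0L) stop("branch before any atom at position ", pos,
                           " in '", smiles, "'")
      stack <- c(stack, prev)
    } else if (ch == ")") {
      if (!length(stack)) stop("unmatched ')' at position ", pos,
                               " in '", smiles, "'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (grepl("^[1-9]$", ch)) {
      if (prev == 0L) stop("ring digit before any atom at position ", pos,
                           " in '", smiles, "'")
      key <- ch
      if (is.null(rings[[key]])) {
        rings[[key]] <- c(prev, pending_bond)
      } else {
        open <- rings[[key]]
        o <- max(open[2L], pending_bond)
        add_edge(open[1L], prev, o)
        rings[[key]] <- NULL
      }
      pending_bond <- 1L
    } else {
      stop("unsupported SMILES token '", ch, "' at position ", pos,
           " in '", smiles, "'")
    }
  }
  if (length(stack)) stop("unclosed branch '(' in '", smiles, "'")
  open_rings <- names(rings)[!vapply(rings, is.null, logical(1))]
  if (length(open_rings)) {
    stop("unclosed ring closure digit(s) ", paste(open_rings, collapse = ", "),
         " in '", smiles, "'")
  }
  if (nrow(edges)) {
    key <- paste(edges[, 1L], edges[, 2L])
    if (anyDuplicated(key)) stop("duplicate bond in '", smiles, "'")
  }
  structure(list(
    n = length(atom),
    atom = atom,
    edges = edges,
    bond_order = order,
    charge = integer(length(atom)),
    smiles = smiles
  ), class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$n, " atoms, ", nrow(x$edges), " bonds: ",
      x$smiles, "\n", sep = "")
  invisible(x)
}

# Per-atom degree of a mol_graph.
mol_degree <- function(g) {
  deg <- integer(g$n)
  if (nrow(g$edges)) {
    t1 <- tabulate(g$edges[, 1L], g$n)
    t2 <- tabulate(g$edges[, 2L], g$n)
    deg <- t1 + t2
  }
  deg
}

# Adjacency list: for each atom, the indices of bonded atoms.
mol_neighbors <- function(g) {
  nb <- vector("list", g$n)
  for (k in seq_len(nrow(g$edges))) {
    i <- g$edges[k, 1L]; j <- g$edges[k, 2L]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}
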