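# Tabular I/O for the four input kinds and the prediction output.
# All files are UTF-8 TSV with a mandatory header row; entity and relation
# vocabularies are 0-based and assigned in first-appearance order so that
# re-reading a file always yields the same token -> index map.

RELATION_SET <- c("side_effect", "protein", "disease")

read_tsv_strict <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Build a 0-based first-appearance vocabulary from a character vector.
build_vocab <- function(tokens) {
  u <- unique(tokens)
  stats::setNames(seq_along(u) - 1L, u)
}

#' Read a drug table (drug_id, smiles)
#'
#' @param path TSV file with header columns `drug_id` and `smiles`.
#' @return data.frame with columns `drug_id`, `smiles`, row order preserved.
#' @export
read_drug_table <- function(path) {
  df <- read_tsv_strict(path, c("drug_id", "smiles"))
  dup <- df$drug_id[duplicated(df$drug_id)]
  if (length(dup)) {
    stop("duplicate drug_id in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
  empty <- which(!nzchar(trimws(df$smiles)))
  if (length(empty)) {
    stop("empty SMILES at data line ", empty[1L], " of ", path)
  }
  df[, c("drug_id", "smiles")]
}

#' Write a drug table
#' @param drugs data.frame with `drug_id`, `smiles`.
#' @param path output TSV path.
#' @export
write_drug_table <- function(drugs, path) {
  write_tsv_strict(drugs[, c("drug_id", "smiles")], path)
}

#' Read a drug-entity association table
#'
#' Relations are restricted to the closed set side_effect / protein / disease.
#' Duplicate rows are rejected.
#'
#' @param path TSV with columns `drug_id`, `relation`, `entity_id`.
#' @return data.frame with the three columns.
#' @export
read_association_table <- function(path) {
  df <- read_tsv_strict(path, c("drug_id", "relation", "entity_id"))
  bad <- setdiff(unique(df$relation), RELATION_SET)
  if (length(bad)) {
    stop("unknown relation(s) in ", path, ": ", paste(bad, collapse = ", "),
         " (allowed: ", paste(RELATION_SET, collapse = ", "), ")")
  }
  key <- paste(df$drug_id, df$relation, df$entity_id, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate association rows in ", path)
  df[, c("drug_id", "relation", "entity_id")]
}

#' @rdname read_association_table
#' @param assoc association data.frame.
#' @export
write_association_table <- function(assoc, path) {
  write_tsv_strict(assoc[, c("drug_id", "relation", "entity_id")], path)
}

#' Read knowledge-graph triples into an indexed TripleSet
#'
#' Vocabularies are built in first-appearance order (heads then tails row by
#' row). An optional `label` column must hold -1 or 1; when absent every
#' triple is a positive (Y = +1): observed triples are positives, negatives
#' are sampled at training time.
#'
#' @param path TSV with columns `head`, `relation`, `tail` and optional `label`.
#' @return an object of class `triple_set`: list(entity_vocab, relation_vocab,
#'   triples (n x 3 integer matrix, 0-based), labels (+1/-1 integer vector)).
#' @export
read_triples <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  if (nrow(df) == 0L) {
    return(triple_set(character(), character(),
                      matrix(integer(), 0L, 3L), integer()))
  }
  req <- c("head", "relation", "tail")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  labels <- if ("label" %in% names(df)) {
    lab <- suppressWarnings(as.integer(df$label))
    if (any(is.na(lab)) || !all(lab %in% c(-1L, 1L))) {
      stop("triple labels must be -1 or 1 in ", path)
    }
    lab
  } else rep(1L, nrow(df))
  ent_tokens <- as.vector(t(cbind(df$head, df$tail)))  # row-wise head, tail
  evocab <- build_vocab(ent_tokens)
  rvocab <- build_vocab(df$relation)
  tri <- cbind(evocab[df$head], rvocab[df$relation], evocab[df$tail])
  dimnames(tri) <- NULL
  triple_set(names(evocab), names(rvocab), tri, labels)
}

#' Construct a TripleSet from vocabularies and index-coded triples
#' @param entities,relations character token vectors in index order.
#' @param triples n x 3 integer matrix of 0-based (head, relation, tail).
#' @param labels integer vector in \{-1, 1\}.
#' @export
triple_set <- function(entities, relations, triples, labels) {
  triples <- matrix(as.integer(triples), ncol = 3L)
  stopifnot(length(labels) == nrow(triples))
  if (nrow(triples)) {
    stopifnot(max(triples[, 1L], triples[, 3L]) < length(entities),
              max(triples[, 2L]) < length(relations), min(triples) >= 0L)
  }
  structure(list(
    entity_vocab = stats::setNames(seq_along(entities) - 1L, entities),
    relation_vocab = stats::setNames(seq_along(relations) - 1L, relations),
    triples = triples,
    labels = as.integer(labels)
  ), class = "triple_set")
}

#' @export
print.triple_set <- function(x, ...) {
  cat("<triple_set> ", nrow(x$triples), " triples, ",
      length(x$entity_vocab), " entities, ",
      length(x$relation_vocab), " relations (",
      sum(x$labels == 1L), " positive)\n", sep = "")
  invisible(x)
}

#' Write a TripleSet back to TSV
#' @param ts a `triple_set`.
#' @param path output path.
#' @export
write_triples <- function(ts, path) {
  ents <- names(ts$entity_vocab)
  rels <- names(ts$relation_vocab)
  df <- data.frame(head = ents[ts$triples[, 1L] + 1L],
                   relation = rels[ts$triples[, 2L] + 1L],
                   tail = ents[ts$triples[, 3L] + 1L],
                   label = ts$labels)
  write_tsv_strict(df, path)
}

#' Read a DDI pair table
#'
#' Binary mode coerces labels to 0/1 and rejects duplicate unordered pairs
#' (pairs are canonicalised by lexicographic min/max for the duplicate check
#' only; stored order is as given, since DDI is undirected but files may list
#' either orientation). Event mode keeps class tokens and attaches a
#' first-appearance class vocabulary.
#'
#' @param path TSV with columns `drug_a`, `drug_b`, `label`.
#' @param mode "binary" or "event".
#' @return data.frame with attribute `mode`; event mode adds attribute
#'   `class_vocab` (0-based token -> index map).
#' @export
read_pair_table <- function(path, mode = c("binary", "event")) {
  mode <- match.arg(mode)
  df <- read_tsv_strict(path, c("drug_a", "drug_b", "label"))
  pair_table(df$drug_a, df$drug_b, df$label, mode)
}

#' Construct a pair table from vectors
#' @param drug_a,drug_b drug id tokens.
#' @param label binary 0/1 labels or event class tokens.
#' @param mode "binary" or "event".
#' @export
pair_table <- function(drug_a, drug_b, label, mode = c("binary", "event")) {
  mode <- match.arg(mode)
  drug_a <- as.character(drug_a)
  drug_b <- as.character(drug_b)
  selfp <- which(drug_a == drug_b)
  if (length(selfp)) {
    stop("self-pair (", drug_a[selfp[1L]], ", ", drug_b[selfp[1L]],
         ") at row ", selfp[1L])
  }
  df <- data.frame(drug_a = drug_a, drug_b = drug_b,
                   label = as.character(label))
  if (mode == "binary") {
    lab <- suppressWarnings(as.integer(df$label))
    if (any(is.na(lab)) || !all(lab %in% c(0L, 1L))) {
      stop("binary labels must be 0 or 1")
    }
    df$label <- lab
    canon <- paste(pmin(df$drug_a, df$drug_b), pmax(df$drug_a, df$drug_b),
                   sep = "\r")
    if (anyDuplicated(canon)) {
      stop("duplicate unordered drug pair in binary mode: ",
           sub("\r", " / ", canon[duplicated(canon)][1L]))
    }
  } else {
    attr(df, "class_vocab") <- build_vocab(df$label)
  }
  attr(df, "mode") <- mode
  df
}

#' Write per-pair prediction scores
#'
#' @param pairs pair table (or any data.frame with drug_a/drug_b).
#' @param scores numeric vector (binary) or matrix with one column per class,
#'   aligned 1:1 with `pairs` rows; probabilities in [0, 1].
#' @param path output TSV path; scores written with 6 decimals.
#' @export
write_predictions <- function(pairs, scores, path) {
  scores <- if (is.matrix(scores)) scores else matrix(scores, ncol = 1L)
  if (nrow(scores) != nrow(pairs)) {
    stop("scores (", nrow(scores), ") not aligned with pairs (",
         nrow(pairs), ")")
  }
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  cn <- colnames(scores)
  if (is.null(cn)) {
    cn <- if (ncol(scores) == 1L) "score" else paste0("class_", seq_len(ncol(scores)) - 1L)
  }
  out <- data.frame(drug_a = pairs$drug_a, drug_b = pairs$drug_b,
                    check.names = FALSE)
  for (j in seq_len(ncol(scores))) out[[cn[j]]] <- sprintf("%.6f", scores[, j])
  write_tsv_strict(out, path)
}

#' Write a pair table
#' @param pairs pair table data.frame.
#' @param path output path.
#' @export
write_pair_table <- function(pairs, path) {
  write_tsv_strict(pairs[, c("drug_a", "drug_b", "label")], path)
}
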