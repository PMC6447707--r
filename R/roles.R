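## Helper/beneficiary role classification from gene content, and the
## cellodextrin cross-feeding interaction network.

DOWNSTREAM_FEATURES <- c("beta_glucosidase", "six_phospho_beta_glucosidase",
                         "cellobiose_phosphorylase")
TRANSPORTER_FEATURES <- c("pts_cel", "abc_ceb")

#' Build a taxon (or bin) x role-feature presence matrix
#'
#' A feature is present in a group iff at least one gene of the group
#' carries the corresponding label. Annotation EC labels map to role
#' features; any `PTS_Cel*` transporter maps to `pts_cel`, any `ABC_*` to
#' `abc_ceb`.
#'
#' @param annotations data.frame from [annotate_contigs()]`$annotations`
#'   (columns `genus`, `ec_labels`, `transporters`; a `bin` column when
#'   grouping by bin).
#' @param grouping `"taxon"` (group by `genus`, dropping `"unassigned"`)
#'   or `"bin"`.
#' @return logical matrix groups x `role_features()` of class
#'   `gene_content_matrix`.
#' @export
build_gene_content_matrix <- function(annotations, grouping = c("taxon", "bin")) {
  grouping <- match.arg(grouping)
  feats <- role_features()
  if (!nrow(annotations)) {
    m <- matrix(logical(0), 0, length(feats),
                dimnames = list(character(0), feats))
    class(m) <- c("gene_content_matrix", class(m))
    return(m)
  }
  key <- if (grouping == "taxon") annotations$genus else annotations$bin
  if (is.null(key)) stop("annotations lack a '", grouping, "' grouping column")
  ann <- annotations[!is.na(key) & key != "unassigned", , drop = FALSE]
  key <- key[!is.na(key) & key != "unassigned"]
  groups <- sort(unique(key))
  m <- matrix(FALSE, length(groups), length(feats),
              dimnames = list(groups, feats))
  for (i in seq_along(key)) {
    labels <- c(strsplit(ann$ec_labels[i], ";", fixed = TRUE)[[1]],
                strsplit(ann$transporters[i], ";", fixed = TRUE)[[1]])
    for (l in labels) {
      f <- switch(l,
                  "EC:3.2.1.4" = "endoglucanase",
                  "EC:3.2.1.21" = "beta_glucosidase",
                  "EC:3.2.1.86" = "six_phospho_beta_glucosidase",
                  "cellobiose_phosphorylase" = "cellobiose_phosphorylase",
                  if (grepl("^PTS_", l)) "pts_cel"
                  else if (grepl("^ABC_", l)) "abc_ceb" else NA_character_)
      if (!is.na(f)) m[key[i], f] <- TRUE
    }
  }
  empty <- rownames(m)[rowSums(m) == 0]
  if (length(empty))
    warning("group(s) with no role-feature genes: ",
            paste(empty, collapse = ", "))
  class(m) <- c("gene_content_matrix", class(m))
  m
}

#' Classify taxa into helpers, beneficiaries and non-participants
#'
#' A taxon is a *helper* iff it carries endoglucanase plus at least one
#' downstream assimilation gene (beta-glucosidase, 6-phospho-beta-
#' glucosidase or cellobiose phosphorylase); a *beneficiary* iff it lacks
#' endoglucanase but carries at least one downstream gene; otherwise a
#' non-participant. A helper or beneficiary with neither characterized
#' cellodextrin transporter family is flagged
#' `"unclassified_possible"` (it plausibly encodes an uncharacterized
#' transporter); all others are `"classified"`. An endoglucanase-only
#' taxon is a helper with a no-assimilation warning.
#'
#' @param matrix logical taxa x `role_features()` matrix (rownames =
#'   taxa); a `gene_content_matrix` or any logical/0-1 matrix with those
#'   columns.
#' @return data.frame with columns `taxon`, `role`, `transporter_status`,
#'   `evidence`.
#' @export
classify_roles <- function(matrix) {
  m <- matrix
  need <- setdiff(role_features(), colnames(m))
  if (length(need)) stop("matrix lacks feature column(s): ",
                         paste(need, collapse = ", "))
  m <- m[, role_features(), drop = FALSE] > 0
  out <- lapply(rownames(m), function(tx) {
    row <- m[tx, ]
    endo <- row[["endoglucanase"]]
    down <- any(row[DOWNSTREAM_FEATURES])
    role <- if (endo && down) "helper"
            else if (endo) "helper"   # endoglucanase-only: see warning below
            else if (down) "beneficiary"
            else "non_participant"
    if (endo && !down)
      warning("taxon ", tx, ": endoglucanase without assimilation genes; ",
              "classified as helper (no-assimilation)")
    transporter <- if (role == "non_participant") "classified"
      else if (!any(row[TRANSPORTER_FEATURES])) "unclassified_possible"
      else "classified"
    data.frame(taxon = tx, role = role, transporter_status = transporter,
               evidence = paste(names(row)[row], collapse = ";"))
  })
  do.call(rbind, out)
}

#' Build the cellodextrin cross-feeding interaction network
#'
#' Nodes are the classified taxa plus one shared cellodextrin pool;
#' helpers produce into the pool, every helper and beneficiary consumes
#' from it, and the pool carries a single product-inhibition edge back to
#' endoglucanase expression.
#'
#' @param assignments data.frame from [classify_roles()].
#' @return object of class `interaction_network`: list with `nodes`
#'   (data.frame `node`, `type`) and `edges` (data.frame `from`, `to`,
#'   `type`).
#' @export
build_network <- function(assignments) {
  if (!nrow(assignments)) stop("need at least one role assignment")
  pool <- "cellodextrin_pool"
  nodes <- data.frame(node = c(assignments$taxon, pool),
                      type = c(assignments$role, "pool"))
  edges <- data.frame(from = character(0), to = character(0),
                      type = character(0))
  for (i in seq_len(nrow(assignments))) {
    tx <- assignments$taxon[i]; role <- assignments$role[i]
    if (role == "helper")
      edges[nrow(edges) + 1L, ] <- list(tx, pool, "produces")
    if (role %in% c("helper", "beneficiary"))
      edges[nrow(edges) + 1L, ] <- list(pool, tx, "consumes")
  }
  if (any(assignments$role == "helper"))
    edges[nrow(edges) + 1L, ] <- list(pool, "endoglucanase_expression",
                                      "inhibits")
  structure(list(nodes = nodes, edges = edges), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network:", nrow(x$nodes), "nodes,",
      sum(x$edges$type == "produces"), "produces /",
      sum(x$edges$type == "consumes"), "consumes /",
      sum(x$edges$type == "inhibits"), "inhibits edges\n")
  invisible(x)
}

#' Role recovery against simulator truth
#'
#' @param assignments data.frame from [classify_roles()].
#' @param truth data.frame with columns `taxon` (or `genus`) and `role`
#'   covering every assigned taxon.
#' @return list with `confusion` (3x3 matrix truth x predicted) and
#'   `accuracy`.
#' @export
role_recovery <- function(assignments, truth) {
  if ("genus" %in% names(truth) && !("taxon" %in% names(truth)))
    truth$taxon <- truth$genus
  i <- match(assignments$taxon, truth$taxon)
  if (anyNA(i)) stop("truth does not cover taxa: ",
                     paste(assignments$taxon[is.na(i)], collapse = ", "))
  lev <- c("helper", "beneficiary", "non_participant")
  confusion <- table(factor(truth$role[i], levels = lev),
                     factor(assignments$role, levels = lev),
                     dnn = c("truth", "predicted"))
  list(confusion = confusion,
       accuracy = sum(diag(confusion)) / sum(confusion))
}
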