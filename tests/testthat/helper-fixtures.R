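# Shared fixtures: packaged ontology/resources/KB are read once; small
# synthetic ontologies are built in code per test.

ont <- thbp_ontology()
res <- thbp_resources()

# write a throwaway ontology JSON from a list of records
write_ontology_json <- function(records, path = tempfile(fileext = ".json")) {
  jsonlite::write_json(records, path, auto_unbox = TRUE, null = "null")
  path
}

# filler words for hand-built explanation streams (disjoint from the
# ontology by construction; asserted in test-fixtures.R)
test_fillers <- c("quartz", "melody", "garden", "lantern", "pebble",
                  "canyon", "harbor", "meadow", "timber", "copper")

# parts with single-token formal names, usable in planted explanations
plantable_parts <- c("heart", "lung", "colon", "kidney", "liver", "stomach",
                     "spleen", "brain", "throat", "trachea", "bladder",
                     "knee", "vein", "artery", "bone", "blood", "nerve",
                     "muscle", "skin")

# build a token stream with the given parts planted at the given offsets
build_stream <- function(offset_sets, ontology = ont) {
  total <- max(unlist(offset_sets)) + 3L
  tokens <- rep(test_fillers, length.out = total)
  for (id in names(offset_sets)) {
    tokens[offset_sets[[id]] + 1L] <-
      stem_and_clean(ontology$nodes[[id]]$formal_name)
  }
  tokens
}

# draw a random set of candidate offset lists (distinct parts, disjoint
# strictly-positive-probability offsets); used by the oracle-equivalence
# property suites
random_offset_sets <- function(k = NULL) {
  if (is.null(k)) k <- sample(2:4, 1)
  parts <- sample(plantable_parts, k)
  pool <- sample(0:80)
  sets <- list()
  taken <- 0L
  for (p in parts) {
    cnt <- sample(1:5, 1)
    sets[[p]] <- sort(pool[(taken + 1L):(taken + cnt)])
    taken <- taken + cnt
  }
  sets
}

naive_plural <- function(word) {
  irregular <- c(foot = "feet", tooth = "teeth", pancreas = "pancreases",
                 uterus = "uteruses", pelvis = "pelvises",
                 esophagus = "esophaguses")
  if (word %in% names(irregular)) return(unname(irregular[word]))
  if (grepl("(s|x|z|ch|sh)$", word)) return(paste0(word, "es"))
  if (grepl("[^aeiou]y$", word)) return(sub("y$", "ies", word))
  paste0(word, "s")
}
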