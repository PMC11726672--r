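#!/usr/bin/env Rscript
# Explicit, opt-in download of the experimental coordinate files used by
# the accession-based acceptance tier. The package itself never touches
# the network; run this once to populate tests/testthat/pdb-cache/.
#
#   Rscript scripts/fetch_pdb.R

dest <- file.path("tests", "testthat", "pdb-cache")
dir.create(dest, showWarnings = FALSE, recursive = TRUE)

# receptor chains of the mu-opioid structure set: the fentanyl-bound
# hMOR-Gi target plus the BLAST-derived MOR hits and the mMOR-nanobody
# inactive state
entries <- data.frame(
  id    = c("4dkl", "8qot", "7ul4", "8e0g", "5c1m", "6dde",
            "8f7r", "8f7q", "8ef5", "8efb", "7sbf"),
  chain = c("A", "A", "A", "A", "A", "R", "M", "M", "R", "R", "R"),
  stringsAsFactors = FALSE
)

for (id in entries$id) {
  path <- file.path(dest, paste0(id, ".pdb"))
  if (file.exists(path)) next
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
  message("fetching ", url)
  utils::download.file(url, path, quiet = TRUE, mode = "wb")
}

# ensemble manifest: 12 chains (8EF5 contributes both R and M)
man <- rbind(entries, data.frame(id = "8ef5", chain = "M"))
man <- data.frame(path = paste0(man$id, ".pdb"), chain = man$chain,
                  label = paste0(toupper(man$id), "_", man$chain))
jsonlite::write_json(man, file.path(dest, "ensemble_manifest.json"),
                     pretty = TRUE)
message("cached ", nrow(man), " ensemble members under ", dest)
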