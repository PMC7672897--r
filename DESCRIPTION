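Package: clustasm
Title: Clustering-Oriented De Novo Assembly of Illumina-Style Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A de novo assembler for substitution-error short reads built
    around error-tolerant k-mer clustering. All k-mers are clustered by
    Hamming distance (allowing up to p mismatches, directly or via reverse
    complement) using a pigeonhole (p+1)-substring index, each cluster is
    replaced by its consensus k-mer (with recursive splitting of over-merged
    clusters), and a de Bruijn graph is built on the consensus set, cleaned
    (low-frequency edges, tips, bubbles, chimeric connections), extended with
    sub-k overlaps and scaffolded with read pairs. Includes an Illumina-like
    paired-read simulator and assembly summary statistics (N50, E-size).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
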