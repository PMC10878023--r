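# Shared fixture builders: every fixture is constructed in code at test
# time; nothing binary is stored.

# quick variant-record data frame with sensible defaults, for callsets
rec <- function(chrom = "c1", pos = 100L, ref = "A", alt = "T",
                qual = 500, FS = NA_real_, QD = NA_real_, MQ = NA_real_,
                SOR = NA_real_, MQRankSum = NA_real_,
                ReadPosRankSum = NA_real_, gt = "0/1", depth = 30L,
                alt_reads = 15L, n_alt = 1L) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             vtype = ifelse(nchar(ref) == 1L & nchar(alt) == 1L,
                            "SNV", "INDEL"),
             qual = qual, FS = FS, QD = QD, MQ = MQ, SOR = SOR,
             MQRankSum = MQRankSum, ReadPosRankSum = ReadPosRankSum,
             gt = gt, depth = as.integer(depth),
             alt_reads = as.integer(alt_reads), n_alt = as.integer(n_alt),
             stringsAsFactors = FALSE)
}

callset_of <- function(..., clone = "A") {
  clone_callset(do.call(rbind, list(...)), clone)
}

# constant-depth coverage track over whole chromosomes
flat_coverage <- function(lengths, depth = 30L) {
  do.call(rbind, lapply(names(lengths), function(ch) {
    data.frame(chrom = ch, pos = seq_len(lengths[[ch]]),
               depth = as.integer(depth), stringsAsFactors = FALSE)
  }))
}

# reduced-scale simulation parameters for whole-pipeline checks
small_sim_params <- function() {
  default_sim_params(
    chrom_lengths = c(chr1 = 120000L, chr2 = 120000L),
    n_blocks = data.frame(chrom = "chr1", start = 60000L, width = 150L),
    category_counts = data.frame(mismatches = c(2L, 4L),
                                 pam = c("NGG", "NAG"),
                                 bulge = c("none", "none"),
                                 count = c(3L, 3L)),
    n_shared_snv = 150L, n_shared_indel = 40L, n_unique_indel_a = 40L,
    n_unique_indel_b = 40L, n_diff_geno = 10L, n_drift = 5L,
    cnvs_a = data.frame(chrom = "chr2", start = 0L, end = 50000L,
                        cnv_type = "deletion", mult = 0.45),
    cnvs_shared = data.frame(chrom = "chr1", start = 80000L,
                             end = 110000L, cnv_type = "duplication",
                             mult = 1.4),
    artifacts_a = data.frame(chrom = "chr2", start = 60000L,
                             end = 110000L, mult = 0.45))
}

# ten-record hand-checked VCF with two samples, one multi-allelic record
# and one symbolic ALT
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=c1,length=100000>",
    "##contig=<ID=c2,length=50000>",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"FS\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"QD\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    "c1\t100\t.\tA\tT\t900\tPASS\tFS=3.2;QD=20;MQ=59\tGT:AD:DP\t0/1:12,8:20\t0/0:30,0:30",
    "c1\t250\t.\tG\tC\t700\tPASS\tFS=1.0;QD=25\tGT:AD:DP\t1/1:0,22:22\t0/1:10,10:20",
    "c1\t300\t.\tT\tTA\t660\tPASS\tQD=18\tGT:AD:DP\t0/1:9,7:16\t0/0:25,0:25",
    "c1\t400\t.\tCTT\tC\t500\tPASS\tFS=7.5\tGT:AD:DP\t0/1:14,11:25\t0/1:12,9:21",
    "c1\t500\t.\tA\tG,C\t800\tPASS\tMQ=55\tGT:AD:DP\t1/2:2,10,9:21\t0/1:11,9,0:20",
    "c1\t600\t.\tT\t<DEL>\t300\tPASS\tMQ=44\tGT:AD:DP\t0/1:8,6:14\t0/0:20,0:20",
    "c1\t700\t.\tG\tA\t90\tPASS\tFS=61.5;QD=1.2\tGT:AD:DP\t0/1:15,13:28\t0/0:22,0:22",
    "c2\t150\t.\tC\tCGG\t450\tPASS\tFS=2.0;QD=12\tGT:AD:DP\t0/1:10,10:20\t0/0:18,0:18",
    "c2\t900\t.\tAAC\tA\t610\tPASS\tFS=4.4\tGT:AD:DP\t1|0:13,12:25\t0/0:27,0:27",
    "c2\t950\t.\tG\tT\t820\tPASS\tFS=0.8;QD=28;MQ=60\tGT:AD:DP\t./.:.:.\t1/1:0,31:31"
  )
  writeLines(lines, path)
  path
}
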