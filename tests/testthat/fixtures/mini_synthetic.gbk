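LOCUS       MINISYN                  420 bp    DNA     linear   SYN 01-JAN-2020
DEFINITION  Synthetic mini contig for parser tests.
ACCESSION   MINISYN
FEATURES             Location/Qualifiers
     source          1..420
     CDS             10..45
                     /locus_tag="cdsA"
                     /translation="MKLVVGGHELV"
     CDS             complement(61..96)
                     /locus_tag="cdsB"
     CDS             join(121..150,181..210)
                     /locus_tag="cdsC"
ORIGIN
        1 acgtacgtaa tgaaactggt tgttggtggt catgaactgg tttaacgtac gtacgtacgt
       61 ttacagttcg tgaccaccaa caaccagcat acgtacgtac gtacgtacgt acgtacgtac
      121 atgggtggtc atgaactggt tgttaaaggt acgtacgtac gtacgtacgt acgtacgtac
      181 gaactggttg ttaaaggtca tcatcattaa acgtacgtac gtacgtacgt acgtacgtac
      241 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt
      301 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt
      361 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt
//
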