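LOCUS       SYNTOY001        1500 bp    DNA     circular VRT
DEFINITION  synthetic toy mitochondrion, complete genome.
ACCESSION   SYNTOY001
SOURCE      synthetic toy
  ORGANISM  synthetic toy
FEATURES             Location/Qualifiers
     source          1..1500
     tRNA            1..68
                     /gene="tRNA-Phe"
                     /anticodon="GAA"
     rRNA            69..300
                     /gene="12S-rRNA"
     CDS             301..600
                     /gene="ND1"
     tRNA            601..670
                     /gene="tRNA-Ile"
                     /anticodon="GAT"
     CDS             671..1000
                     /gene="ND2"
     tRNA            complement(995..1064)
                     /gene="tRNA-Gln"
                     /anticodon="TTG"
     CDS             1065..1364
                     /gene="COI"
     D-loop          1365..1430
                     /gene="CR"
     tRNA            join(1431..1500,1..6)
                     /gene="tRNA-Thr"
                     /anticodon="TGT"
ORIGIN
        1 gcttctccga ggtccgagaa aatgtattaa caagttagat ggtcgccatt atccttaaca
       61 acctctgtca tatcctaata aacatcgcag cgtatatcgt atacataaat attacggaca
      121 gatatactgg caactttaat gcactgcatc ccgatcaaca atgattatcc gtctctcatt
      181 agctagttta aaaaaaccgg gatagaccag tgccgcataa acgcagcgac aagatgcatg
      241 caccaactat caacacaata aactatcagg aaaatctacg ttacacggta tggtccttga
      301 atctgagtag aatccaagta gtcgccggca agctacgggg cttgcctctc gcgtcattct
      361 tattttatct tggactaata acattcgtgc tagatgggat cgtgaatcgt acaccttcta
      421 agttagactg tatttgaggc acgacgccca ttcatccttt gatcccctca cacacactag
      481 ttgcgagcac ggattgagct gcccgacctg aacgcatcag ctcgttataa tgcttatctc
      541 tcctataatt ccagacatcg tcttgatatt ctaaccgagt aatcgtcctt taggagatct
      601 ttatctgagt ttcctgtcgt tcaaagatgc cgcacggcac aatctaatgc caattgatct
      661 ctacgaccga atgcaacctg atactccata gcactaagga cttataacaa cgtctagaat
      721 catgaaattt aacgcatcaa gaccctccct ctcaccgaat ctcctgccgc taaatcccgg
      781 cgtatcatga ttccctaaca gatatcacga aatccctctc gccatatata ccaaaaactt
      841 acgtctcctt cagcattcgg gggcgtacgc ggaaatacct atgtcccttc ccagcatcct
      901 actcatattt gatatcaaga tgtatcggac cactgagcat tacacccccc cccaacaatc
      961 tgagatttaa tgcgttccgg cgcttccaat ctattcattt tcattcctgc acacgtctat
     1021 catcacttaa ataccccaaa agcaatagcg ggagtatttt ataacttatg ggccagaact
     1081 atccttagcc gtttaacacc tgtctactcc taaagccctc gtgaatccaa tgcatgcaat
     1141 atagttattg gaagctgcac actcagattc ctccatgagt ctaaacttca ccccgatccc
     1201 aagttgcttg agccaccccg aagtacgctg aatagtcacc taacccacca tccaatcgca
     1261 acacatcaag gtattattgc aacctttgtg atacggctaa gcagcccctc gtatctcgcc
     1321 taaacctcaa ttactccaca tacccaaact atcccgtaac cttgtggatc catccgaaag
     1381 cacgtagatc aaccgtgaat aagtctacct acccaatttc ccctcctagc cccagatttt
     1441 taacaccaat gttcggtaca aggtatcaaa ctgctcgcaa ctactcataa ctcccaggcc
//
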