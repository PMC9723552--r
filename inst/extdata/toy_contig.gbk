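LOCUS       TOYCTG01                 240 bp    DNA     linear   BCT 01-JAN-2020
DEFINITION  Synthetic toy contig for parser examples.
ACCESSION   TOYCTG01
VERSION     TOYCTG01.1
SOURCE      synthetic construct
  ORGANISM  synthetic construct
FEATURES             Location/Qualifiers
     source          1..240
     gene            1..60
                     /locus_tag="TOY_0001"
     CDS             1..60
                     /locus_tag="TOY_0001"
                     /product="SusC-like TonB-dependent transporter"
     gene            complement(81..140)
                     /locus_tag="TOY_0002"
     CDS             complement(81..140)
                     /locus_tag="TOY_0002"
                     /product="glycoside hydrolase family 92"
     gene            161..220
                     /locus_tag="TOY_0003"
     CDS             161..220
                     /locus_tag="TOY_0003"
                     /product="arylsulfatase"
ORIGIN
        1 acgtacgtac acgtacgtac acgtacgtac acgtacgtac acgtacgtac acgtacgtac
       61 acgtacgtac acgtacgtac acgtacgtac acgtacgtac acgtacgtac acgtacgtac
      121 acgtacgtac acgtacgtac acgtacgtac acgtacgtac acgtacgtac acgtacgtac
      181 acgtacgtac acgtacgtac acgtacgtac acgtacgtac acgtacgtac acgtacgtac
//
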