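enzyme,enzyme_class,description,substrate,fluorophore,ec
leucyl aminopeptidase,peptidase,exopeptidase,L-leucine-AMC,AMC,3.4.11.1
arginyl aminopeptidase,peptidase,exopeptidase,L-arginine-AMC,AMC,3.4.11.6
prolyl aminopeptidase,peptidase,exopeptidase,L-proline-AMC,AMC,3.4.11.5
ornithyl aminopeptidase,peptidase,exopeptidase,ornithine-AMC,AMC,na
gingipain,peptidase,endopeptidase,Z-Phe-Arg-AMC,AMC,3.4.22.37
clostripain,peptidase,endopeptidase,Z-Phe-Val-Arg-AMC,AMC,3.4.22.8
beta-xylosidase,glycosylase,glycosyl hydrolase,MUB-beta-D-xylopyranoside,MUB,3.2.1.37
beta-cellobiohydrolase,glycosylase,glycosyl hydrolase,MUB-beta-D-cellobioside,MUB,3.2.1.91
N-acetyl-beta-glucosaminidase,glycosylase,glycosyl hydrolase,MUB-N-acetyl-beta-D-glucosaminide,MUB,3.2.1.52
beta-glucosidase,glycosylase,glycosyl hydrolase,MUB-beta-D-glucopyranoside,MUB,3.2.1.21
alpha-glucosidase,glycosylase,glycosyl hydrolase,MUB-alpha-D-glucopyranoside,MUB,3.2.1.20
alkaline phosphatase,phosphatase,phosphomonoesterase,MUB-PO4,MUB,3.1.3.1
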