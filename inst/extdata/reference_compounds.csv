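name,formula,class,note
FA(20:1) Gondoic acid,C20H38O2,FA,
FA(22:1) Erucic acid,C22H42O2,FA,
FA(24:1) Nervonic acid,C24H46O2,FA,
FA(26:1) Ximenic acid,C26H50O2,FA,
FA(20:0) Arachidic acid,C20H40O2,FA,
FA(22:0) Behenic acid,C22H44O2,FA,
FA(24:0) Lignoceric acid,C24H48O2,FA,
FA(26:0) Cerotic acid,C26H52O2,FA,
FA(18:0) Stearic acid,C18H36O2,FA,
FA(18:1) Oleic acid,C18H34O2,FA,
FA(16:0) Palmitic acid,C16H32O2,FA,
PE(P-36:1),C41H78NO7P,PEp,putative composition for m/z 726.544
PE(P-34:1),C39H74NO7P,PEp,putative composition for m/z 698.513
LysoPE(18:0),C23H48NO7P,LysoPE,
PE(P-38:4),C43H78NO7P,PEp,putative composition for m/z 750.544
PE(P-38:3),C43H80NO7P,PEp,putative composition for m/z 752.560
PS(38:4),C44H78NO10P,PS,
PE(P-40:6),C45H78NO7P,PEp,putative composition for m/z 774.544
Oxidized PS,C48H88NO13P,PS,putative composition for m/z 916.592
Oxidized PC/PS,C52H96NO10P,PC,putative composition for m/z 924.670
Oxidized PG,C51H91O11P,PG,putative composition for m/z 909.623
PE species,C53H90NO6P,PE,putative composition for m/z 866.641
PA species,C54H83O8P,PA,putative composition for m/z 889.573
TG-related species,C47H93O7P,TG,best-fit putative composition for m/z 799.659
LysoPI(18:1),C27H49O12P,LysoPI,
Succinylacetoacetate,C8H10O6,other,shares formula with ethyl aconitate
Ethyl aconitate,C8H10O6,other,shares formula with succinylacetoacetate
Stearoylcarnitine,C25H49NO4,other,
L-Carnitine,C7H15NO3,other,
Leucine-enkephalin,C28H37N5O7,other,lockmass reference
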