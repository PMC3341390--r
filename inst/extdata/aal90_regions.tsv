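abbreviation	name	category	lobe
SFGdor	Superior frontal gyrus, dorsalateral	Association	Frontal
SFGorb	Superior frontal gyrus, orbital	Paralimbic	Frontal
SFGmed	Superior frontal gyrus, medial	Association	Frontal
SFGmorb	Superior frontal gyrus, medial orbital	Paralimbic	Frontal
MFG	Middle frontal gyrus	Association	Frontal
MFGorb	Middle frontal gyrus, orbital	Paralimbic	Frontal
IFGoper	Inferior frontal gyrus, opercular	Association	Frontal
IFGtri	Inferior frontal gyrus, triangular	Association	Frontal
IFGorb	Inferior frontal gyrus, orbital	Paralimbic	Frontal
REG	Gyrus rectus	Association	Frontal
ACC	Anterior cingulate gyrus	Paralimbic	Frontal
OLF	Olfactory cortex	Paralimbic	Frontal
PreCG	Precentral gyrus	Primary	Central
SMA	Supplementary motor area	Association	Central
ROL	Rolandic operculum	Association	Central
MCC	Median- and para- Cingulate gyrus	Paralimbic	Central
CAL	Calcarine fissure and surrounding cortex	Primary	Occipital
CUN	Cuneus	Association	Occipital
LING	Lingual gyrus	Association	Occipital
SOG	Superior occiptal gyrus	Association	Occipital
MOG	Middle occiptal gyrus	Association	Occipital
IOG	Inferior occiptal gyrus	Association	Occipital
FG	Fusiform gyrus	Association	Occipital
SPG	Superior parietal gyrus	Association	Parietal
PCL	Paracentral lobule	Association	Parietal
PoCG	Postcentral gyrus	Primary	Parietal
IPG	Inferior parietal gyrus	Association	Parietal
SMG	Supramarginal gyrus	Association	Parietal
ANG	Angular gyrus	Association	Parietal
PCUN	Precuneus	Association	Parietal
PCC	Posterior cingulate gyrus	Association	Parietal
INS	Insula	Paralimbic	Insula
THA	Thalamus	Subcortical	Subcortical
STG	Superior temporal gyrus	Association	Temporal
STGp	Superior temporal gyrus, temporal pole	Paralimbic	Temporal
MTG	Middle temporal gyrus	Association	Temporal
MTGp	Middle temporal gyrus, temporal pole	Paralimbic	Temporal
ITG	Inferior temporal gyrus	Paralimbic	Temporal
HES	Heschl gyrus	Primary	Temporal
HIP	Hippocampus	Paralimbic	Temporal
PHIP	Parahippocampal gyrus	Paralimbic	Temporal
AMG	Amygdala	Paralimbic	Temporal
CAU	Caudate nucleus	Subcortical	Subcortical
PUT	Lenticular nucleus, putamen	Subcortical	Subcortical
PAL	Lenticular nucleus, pallidum	Subcortical	Subcortical
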