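precursor_symbol	start	end	SZ_KCl	SZ_basal	HC_KCl	HC_basal
ADM	163	183	-	-	+	+
CHGB	88	100	+	+	+	+
CHGB	293	323	-	-	+	+
CHGB	326	332	+	+	+	+
CHGB	440	452	-	-	+	-
CHGB	440	453	-	-	+	-
CHGB	440	454	+	-	+	+
CHGB	440	456	-	-	+	+
CHGB	441	454	-	-	+	-
CHGB	441	456	-	-	+	+
CHGB	442	452	-	-	+	-
CHGB	442	456	-	-	+	-
CHGB	523	535	-	-	+	-
CHGB	527	533	-	-	+	+
CHGB	527	535	-	-	+	-
CHGB	588	596	+	+	+	+
CHGB	588	597	+	+	+	+
CHGB	588	600	-	-	+	-
CHGB	600	613	+	+	+	+
NPPC	24	33	+	+	+	+
NPPC	24	72	-	-	-	-
NPPC	34	72	-	-	+	+
NPPC	46	69	-	-	-	-
NTS	151	158	-	-	+	-
NTS	151	160	-	-	+	+
SST	89	100	-	-	+	+
TMSB10	2	44	+	+	+	+
TMSB4X	2	19	-	-	+	+
TMSB4X	2	44	+	+	+	+
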