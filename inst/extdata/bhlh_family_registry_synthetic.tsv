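family	supergroup	dna_box	representative_domain
ASCa	A	CACCTG	RRDDQKEKERPRIVNAVINQLKMPMTEFRNVKSHILMEAIKYLSYL
ASCb	A	CACCTG	KRAQAAEKPRFNGVNIVLASLRICVLDMIGEPAGFKKPKTPTLNLAVIYLFGL
MyoD	A	CACCTG	RRMKEIAEKMRCNGVNNFLQCLKMMDDGIHIMFPRRYCCWGDCYKEMKYLILGKAIVYLLEL
E12/E47	A	CACCTG	RKNCFIKFEKIRIDKINSEIIRLKLLVTMIVVWRKKKPAVLGLATMYLIQL
Ngn	A	CACCTG	KRMMGNEKARLSQINGHFYSLKTGARTFKTRYQFVKIGETIMTDKGAKIRVLPSATPYVVAL
NeuroD	A	CACCTG	KRFWVERGRDMALNIMFKKLKCFQNYATDKEWKPPILWSAVSYIWTL
Mist1	A	CACCTG	KKNWDHTLERKRREDVNPQFCDLKAYEWEAAWSDWGLPEQRDGKLRVLHVATCYISKL
Mist	A	CACCTG	KKNALERFRPWTLNFKIMQLRSWDGRHQHICSVFTRCCEHFAKYAKVSILLCATDYLAAL
Delilah	A	CACCTG	RKNKLEKMRNGCLNRWFHDLRHMIQNKRPMKSGVLSDAIPYLYFL
Beta3	A	CACCTG	KRVPWERPRNVTINCDITSLKSSWMTTKNAGTCLCRGRGKEKKQVVLWHAVRYLITL
Oligo	A	CACCTG	RRYDWAHSERARADFLNEHICHLKCRTQRTYECRGILMNFQLKWGKERILCQAVVYIGNL
Net	A	CACCTG	RKAIEPYREKARKRFLNKWFQWLRVPQDRYHRDRPHKMDILWEAIDYVYIL
Mesp	A	CACCTG	RRTLNRKPEKERRCWINCWLCVLKYSFAITGRMGRQGKMDWRDKIPKVHVLYMAIWYLVHL
Twist	A	CACCTG	RRHETMIEKFRFNLINNGIKALKSPVPMIGPRCFEEVAKVIKKSTLYHAVGYLLSL
Paraxis	A	CACCTG	RRSDIERGRCHEVNMPFEALRAMCVATVIKITKWMILLAATCYVHLL
MyoRa	A	CACCTG	RRRESEKVRWMWINEYIALLKVPAKYHNWDNHIFWMLICFVKRPAKHETLYNATPYVYNL
MyoRb	A	CACCTG	RRPYNNNNEKVRWALINCVFYNLRVINDDVEDRVCWQPRRYKWITLMNAVWYIYKL
Hand	A	CACCTG	KKSAHNFPERQRADSLNAKIAMLKYLWNYHRAGHIANRFYKAMVLGLAVWYVWFL
PTFa	A	CACCTG	RRDRCVEKERHWHLNISFNALKMPHFFWCYQIHDKLIKIFTLAGAIIYLNRL
PTFb	A	CACCTG	RKHPSVAIERNRKHDLNGVIFSLRQFYNYSHCRIGKWDILTAATKYLWDL
SCL	A	CACCTG	KKEYSKDEKYRVTCVNEILKVLRMWVKACDEQDGYADPVVVGHPNRDCKEPTLWCATFYIVDL
NSCL	A	CACCTG	KKDCFVERPRCDTVNVMLSWLRWKRQMQVITNQSRAHKYCTLSWAVRYISQL
SRC	B	CACGTG	KRYEQYERNRLYWVNHNILNLRTKSIQGFSAHAGTRAKWVKISTLSEAVWYVNKL
Figa	B	CACGTG	KKESPVTERTRNICINCMLNVLRYQCKPENKIYGTDVFNCGNKIHKAEVLTLAICYLREL
MYC	B	CACGTG	KKYHTVEKNRSEYLNSYIEMLRQHHVLCMVYGAWTAKKIKIAILINAVLYVCHL
Mad	B	CACGTG	KKSGGPANERFRKEWLNVGFAQLKNHTGCFDIQIDPWDDHNKKDKVVVLAMAIRYLNSL
Mnt	B	CACGTG	KKAEGSCERIRCSELNVALGTLKRATLNEGAHMIGVFWDFWRKSMKRKVLRVAIWYVPSL
MAX	B	CACGTG	RKYSFDIERSRGQSINIKFMYLRHYEICTKLCDYKGQGVMNAARGNKLKILEMATKYIEEL
USF	B	CACGTG	KRTVQCGEKERFAHLNNRLQGLRKPMSGIAPEKQPKGFVLHHAVHYISKL
MITF	B	CACGTG	RKHACENIERRRAHKINSLLAVLKTSICLTGRQMKCRILGKATWYLGVL
SREBP	B	CACGTG	RKFYQIEKSRHVILNYVFVSLKEKNSVHALAMREERLKMMRDDRRCKGTILNPAIDYIYYL
AP4	B	CACGTG	RRYHPEKNRFEKLNYKLCRLKELEKVMPKPITVMKYMKVVILGGATFYIRCL
Mlx	B	CACGTG	KRAKWWYEKERFMQLNPSFPNLKTGGAHIFPRCNKGVILDIAVYYLVPL
TF4	B	CACGTG	KKMIGAHIEKIRIKEVNRHLYILRMNQNPFSYARENFKLCVCNRRYRKNYVLTGAVLYVICL
Clock	C	ACGTG	RRVSHPEKFRHSHVNDLFFALKWKKRMSSPVWMDNHMLKNRKKITLVLAVTYVISL
ARNT	C	ACGTG	KRHWGEKDRDFSLNWHLHLLRGDVYKYAPVVRHDQVRVRIHKSVVLTKAIVYLYAL
Bmal	C	ACGTG	RRSRGTEKCRTEQLNQLLHALRERAAQDLGNIRQPKLNKHPTLNTATIYLELL
AHR	C	ACGTG	RKYSKGFEKTRGHNLNGMISHLKFVRCSRWCTYNHMKFAKGLVLGHATTYVVEL
Sim	C	ACGTG	RRHNCMYSEKHREDCINDPIADLKFVVEFWKTDKREILMFAIRYISGL
Trh	C	ACGTG	RRCIACEKGRQSSLNSWLMCLKHESHRQLMVTWAWQIPKTHKAIVLWTAIFYVIFL
HIF	C	ACGTG	KRMIMYLFEKARPAMLNFIFFILKGSFYLPPDHTFNLEDRGKKKMILWTAVAYIEWL
Emc	D		KKQWFCEKQRGFTVNVWLKALRSYKVEWDQVHFKFMKGFILYSAIQYIVAL
Hey	E	CACGCG	RRLADQQQEKFRAVTLNHDLWNLKRCIDYERFFKMTVLAKAINYIFSL
H/E(spl)	E	CACGCG	KRLNIMGAERHRGVDVNYTFYQLRRGLDDQEYDCGVKKCFVCATKFIKHEVLYWAVWYVFAL
Coe	F		KRLDICSEKMRASIINYYLESLRRIWIPSVVVCWKHHKIRILVQATEYLEVL
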