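>crtY synthetic exemplar, lycopene cyclase
GQTPGFISAVEWLGRLMEKGWEYLSIQIRGYGAKGLIYVGMKAFNEIEYLRCRADTDMLT
IGLALDVEPIIMEQGLNRALDTAVPGTTVKGQALVATSAAAHEDPECDDSFLALLGPLHS
IADLILQQFADPVGRWYALWIVAGEEVSRLWGLPARLAAMILKYESTVQGLLTNEYVPML
DMLGTSAQVLAVIESRLGTIRAVQAMEIYGMPGNWQSLDGGHWRNLAEVVRPLNALVDHP
SGALKQQTQEEIGGVTRRLSEALIATVFPPILEGMLMFYDNLCTLPLEHLSFWVTTGDLI

>brp synthetic exemplar, bacterioopsin-related protein / blh beta-carotene dioxygenase
NDGLETIAETTINWRAILMQAWVVLRLESVQFDKDAWALPTKTLSNWIFGNLKSWIQSFP
VDSNKLDGAGLYEIMVVSHLPNAAQSYLMNENLILYSTTNNAAGAGAAIDALEIAGLLYP
LETLIFDEIGLPGKSPALTKQTKGSSFAPSSMLRVTTLIFVQDTNGMLVAVTLVLLPLGS
EFLGEYSQLVGGENRPGFRQGYRTIVVTWDPCGFGISIKLHDFIKLDVFAIVLGYPLRQM
IWLDVQGQGIDGNFSFLPNAAWMPLTGREVALTTGWDVVLKIVSCFAGKHRKERLSVGSS

>crtE synthetic exemplar, geranylgeranyl pyrophosphate synthase
NSKGRFKDYNGAHSKIQIPLHCWIAHEDAVGTARLDIVAFLCRREVGIRKDTYYAKLKIV
DSGVVFSLIDFAALWKGVQLVYGSAFKYSDADLWGALEFLAAYDGVVRQICAWDSRYLGS
ALLSALCKYRSKFPGAGYNKQIAIDYIYHYDSFAASGYWLVRLLYRTPQRFLNVIGVVAG
PIECAGWLIQHWALLIGLTGLSILFAVELLPQLVVALMILELELWGASELVRIRTAGLLS
DPLAVITYLHELWSIAGTHIKAITNQWAQTQGSVSAQMALTAWCNASPDPMFRFIIGNTK

>crtB synthetic exemplar, phytoene synthase
TGPPDKVQPGLSFSRTPAPLEGLVRPLIQLRDRSLHTRSIFGLSYRPLDEGALQGMDTIL
ISGQPPDLVDNRGLQIAIDILGFAEWAKIYGPETYDTRIQDQSWILVCPYEGIHPKGLFP
GETAVEAVLEYKLLYIVLSWVFVPLLHNWAMRLPYAKFHQYGAKHGDVSRDYPLVFLPAQ
EPEENAARTPNWFARCIIHKFFMMFVMGIASKYALVYMPTNGAWLFLRAESRQPSRRRQV
AKEAMPLGYVNDLYTWAQTAVGVLTLFYALSHTHVILLIRVWQSYNADDGATAGANIGPA

>crtI synthetic exemplar, phytoene desaturase
DDGWKIHLIRIRSAEWVFNVYGIHASLLIFSTVKLMKDKIDGMVAGFDAMLDGNLEAILL
YVPAAFSVVIQSLSWFLRTCLKQLARVAPMLITTSALTDEMAVIATLEMGLEVALVPSIE
VSVAPNAPQLCIGNNDPFKPIFHYGIPASGPFFYAKNYCAGWLNTLAVDCRAGDVEDMGI
IGTEGWNYQFGDSAAYSVMTLFASGMHFDNSLKAIIDVPSLTCNAIHMWILIMSIHVNIN
GTTIGKRMTEWMHWSWFGMTWVYRADSGSILSTDPGASFNQAFHVKRDATIDFVAYDKYP

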