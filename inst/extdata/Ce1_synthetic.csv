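D(Sc(z)),Sc(r),v_z,v_r
4.034356322984855581,-0.078909335694501648,0.01076348132275372488,0.00627623223802653302
3.504367570845911661,0.059399262298400354,0.04362408326144946724,0.00350518573369345285
2.501233555102506223,0.082558663803086213,0.05836807916751166753,-0.00128038777469850220
2.003244335653905583,0.081988450186327097,0.06236441707460750605,-0.00213247978429941974
1.631978274609606760,-0.065998175306179158,0.06531425685256392333,0.00426119340808656013
1.204093370086943615,-0.075666784330470749,0.06200191534184416181,-0.00355979231600105604
0.094078663684642905,-0.013317735590417519,0.00932806546773580318,-0.00408771286425961122
4.144725571440246448,0.101250008588712706,0.00097289263045074114,0.00039961640570613664
3.533027887021980007,0.244154209839236691,0.03311627475752671607,-0.00622000161277592827
2.698273589768303893,0.270194482108178924,0.04947045536267576787,-0.00903410363265486592
1.855345621321780047,0.139190048283697770,0.06975725863004371419,-0.00473216115879279697
1.364520053610277284,0.250933742691164030,0.05130598908605981529,0.00223495135338000689
1.085563813939762312,-0.211105223650312313,0.05659985704993258232,-0.00484741212899661867
0.597967615238247596,-0.204782662123440179,0.03896866094186113294,-0.00853763799516148170
3.734725633852828963,0.265359223324432014,0.02555943824460759836,-0.00537291878427546658
3.561281979906086192,0.259098279842045365,0.03019816670527583624,-0.00742886241919249804
2.568037368942840182,0.331654197604594969,0.04514884345310376385,-0.00416933058609041379
1.941339751727019891,-0.284708935965318211,0.04991241268794720937,-0.00037836617270068989
1.525587651482783524,0.294293329447308294,0.05583438046380084785,-0.00038455603110810013
1.125191582545924440,-0.363739645858627891,0.04251067486312042065,-0.00384836399070743887
0.290753619725672596,0.220979662340889782,0.01567853615959407740,0.00683690542854450186
3.831507251003327674,0.338767658498967839,0.01985150570246344004,-0.01557274148505828973
3.182350977931100111,-0.439363098041420541,0.03021038751495446276,0.00137197359256897031
2.776853523546686908,0.495693103415292768,0.02893086220053799409,-0.00925581423168980559
1.892880787324303871,0.429858937623378401,0.04583062090990996928,-0.00173158932088308373
1.275941901990714111,-0.473598015789009119,0.03698106462257588767,-0.00319338825836231952
1.070487097484202899,0.517595427795978558,0.03341511155284450363,0.00835428983938395209
0.448561479590045220,0.402432145822117893,0.01830159077069212423,0.01381179922336718373
3.950583141169940582,0.433028201435269211,0.00284706807479497871,-0.01862289328195871480
3.376203851382105103,0.651890479791361055,0.00779573545354898551,-0.01046462111782569919
2.802524094717004033,-0.566603576852607427,0.02224249190608635837,0.00906195510014908522
2.341011100826570157,-0.569515093234700176,0.01867488277316155590,-0.00282197064819470714
1.572401924596096734,0.558769486809615024,0.01910422319734750296,0.00552005543308541763
0.648558894192012403,-0.563592967896411778,0.00991376611347044231,-0.00809585675498624563
0.235664493739247582,0.435776710744625484,-0.00086509919269768813,0.02435554561939456616
4.077717306735352487,0.378635088122008967,0.00121766460308615114,-0.00830286476817363589
3.497915896442002737,0.734699641029292194,-0.01121574513118444444,-0.01142314472273228687
2.424364245029238418,-0.697316243374786704,-0.00637106713049818453,0.01030987295697170097
2.306850200499265036,0.719445080162092521,-0.00505229788292525447,-0.00322475630281208623
1.384214986384344925,-0.745221995916550140,-0.01137640320364527967,-0.00122811243160589681
1.223323904029810283,-0.787900939444079906,-0.01641649903299335564,-0.00320311546778661747
0.465892835547073059,0.664298049494815412,-0.00747989313034376230,0.02136436624733639364
3.614546948832531470,0.839401790576300710,-0.02063624825540057509,-0.01310282783861135836
3.305011275247670799,-0.843277683984522630,-0.02623276700362900046,0.00553467589209748895
2.810519820292337378,-0.841805680340621532,-0.02171290627024145478,-0.00086286965069540819
2.022335231202081474,0.845671365756009208,-0.02833752656577991080,0.00231063357401092894
1.335732059746694400,-0.819217352339598692,-0.02189186569026695117,-0.00352565398996350452
0.965226334913705575,-0.821618208879068890,-0.02793540635128137495,-0.00473572890587928372
0.492795014374245000,0.791371731478229812,-0.03150591905096833401,0.02478726884036732553
3.876760540952763012,0.035662691220270819,0.01888845850246520866,-0.00267977152414133630
3.411635529613480600,-0.014496081878866432,0.04143903209580364344,0.00421751241867225363
2.785491802638325076,0.129312938914102116,0.05124330988452651531,0.00773057125746785291
1.865007184628540760,-0.104955355232648012,0.05918115174127266953,0.00401311050158669174
1.445791067206300795,-0.058720557443198880,0.06266649551626946035,-0.00074992158027644773
1.196835209731943905,0.019740983351532904,0.06647806313578567827,0.00147337722599769527
0.609957661794929162,-0.020717285683454340,0.05494583783003845895,-0.00145459810711683546
4.004157096962444484,0.098129383446547341,0.01241721599371343673,-0.00701762502795728622
3.021326456118662129,-0.175295994803309430,0.04628169752989312602,0.00008738764798145328
2.906073233064335959,0.209186818666889179,0.04236838571419107580,-0.00178889071798980933
2.376316816662438214,-0.248718990684886038,0.05670639571242806071,0.00034809041689807862
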